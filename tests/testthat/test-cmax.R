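test_that("noiseless logistic dose-response data are refitted exactly", {
  conc <- 10^seq(-3, 1, length.out = 9)
  truth <- list(m = log(0.15), s = 1.3)
  viab <- 1 / (1 + exp(truth$s * (log(conc) - truth$m)))
  fit <- fit_dose_response(conc, viab)
  expect_equal(fit$kind, "logistic2")
  expect_equal(unname(fit$params["m"]), truth$m, tolerance = 1e-6)
  expect_equal(unname(fit$params["s"]), truth$s, tolerance = 1e-6)
  # midpoint concentration -> viability 0.5
  expect_equal(cmax_viability(fit, exp(truth$m))$value, 0.5,
               tolerance = 1e-6)
})

test_that("degenerate and invalid dose-response inputs", {
  conc <- c(0.01, 0.1, 1)
  flat <- fit_dose_response(conc, rep(1, 3))
  expect_equal(flat$kind, "constant")
  expect_equal(cmax_viability(flat, 5)$value, 1)
  # constant slightly above 1 (assay noise) is clipped on evaluation
  high <- fit_dose_response(conc, rep(1.03, 3))
  expect_equal(cmax_viability(high, 0.5)$value, 1)
  expect_error(fit_dose_response(c(1, 2, 2, 1), c(1, 0, 0, 1) ),
               "3 distinct")
  expect_error(fit_dose_response(c(-1, 1, 2), c(1, 0.5, 0)), "positive")
})

test_that("fitted curves are monotone nonincreasing, clipped, and flag
           extrapolation", {
  conc <- 10^seq(-2, 1, length.out = 8)
  set.seed(5)
  viab <- 1 / (1 + exp(0.8 * (log(conc) - log(0.3)))) + rnorm(8, 0, 0.02)
  fit <- fit_dose_response(conc, viab)
  grid <- 10^seq(-4, 3, length.out = 60)
  v <- predict(fit, grid)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v >= 0 & v <= 1))
  expect_true(cmax_viability(fit, 1e-3)$extrapolated)   # below range
  expect_true(cmax_viability(fit, 100)$extrapolated)    # above range
  expect_false(cmax_viability(fit, 0.5)$extrapolated)
})

test_that("CMax viabilities are invariant to point order and replicate
           duplication", {
  conc <- 10^seq(-3, 1, length.out = 9)
  set.seed(11)
  viab <- 1 / (1 + exp(1.1 * (log(conc) - log(0.05)))) +
    rnorm(9, 0, 0.02)
  base <- cmax_viability(fit_dose_response(conc, viab), 0.2)$value
  perm <- sample(9)
  expect_equal(cmax_viability(fit_dose_response(conc[perm], viab[perm]),
                              0.2)$value, base)
  expect_equal(cmax_viability(fit_dose_response(rep(conc, 2),
                                                rep(viab, 2)),
                              0.2)$value, base, tolerance = 1e-8)
})

test_that("PAM discretization matches brute-force k-medoids and analytic
           midpoints", {
  v2 <- c(0.05, 0.1, 0.15, 0.85, 0.9, 0.95)
  m2 <- pam_discretize(v2, 2)
  expect_equal(m2$thresholds, 0.5, tolerance = 1e-9)
  expect_equal(m2$medoids, oracle_kmedoids(v2, 2)$medoids)

  set.seed(3)
  v3 <- c(runif(8, 0, 0.15), runif(8, 0.4, 0.55), runif(8, 0.8, 1))
  m3 <- pam_discretize(v3, 3)
  # optimal medoid sets can tie; the achieved cost must be optimal
  expect_equal(kmedoids_cost(v3, m3$medoids),
               oracle_kmedoids(v3, 3)$cost, tolerance = 1e-12)
  expect_true(all(diff(m3$thresholds) > 0))
  # boundary midpoints between adjacent clusters, analytically
  s <- sort(v3)
  expect_equal(m3$thresholds,
               c((s[8] + s[9]) / 2, (s[16] + s[17]) / 2),
               tolerance = 1e-9)

  expect_error(pam_discretize(rep(0.4, 5), 2), "distinct")
  # medoid-midpoint alternative stays between the same clusters
  mm <- pam_discretize(v3, 3, midpoint = "medoid")
  expect_equal(mm$thresholds,
               c(mean(m3$medoids[1:2]), mean(m3$medoids[2:3])))
})

test_that("threshold application is monotone with ties to the sensitive
           side", {
  m2 <- list(thresholds = 0.5, band_labels = c(1, 0))
  expect_equal(apply_thresholds(c(0.2, 0.5, 0.51), m2), c(1, 1, 0))
  m3 <- list(thresholds = c(0.3, 0.7), band_labels = c(1, 2, 3))
  expect_equal(apply_thresholds(c(0.1, 0.3, 0.5, 0.7, 0.9), m3),
               c(1, 1, 2, 2, 3))
  # monotone: lower viability never maps to a less sensitive class
  set.seed(2)
  v <- sort(runif(50))
  lab <- apply_thresholds(v, m3)
  expect_true(all(diff(lab) >= 0))
})

test_that("drug filtering drops single-class and under-populated drugs", {
  set.seed(9)
  n <- 60
  cells <- sprintf("CL_%02d", 1:n)
  labels <- cbind(
    drug_a = rep(0, n),                       # single class
    drug_b = c(1, rep(0, n - 1)),             # 1 sensitive sample
    drug_c = rep(c(0, 1), each = n / 2))      # balanced
  rownames(labels) <- cells
  sp <- split_spec(cells, c(0.5, 0.25, 0.25), seed = 1)
  res <- filter_analyzable_drugs(labels, sp, min_per_class = 3)
  expect_equal(res$retained, "drug_c")
  rep <- res$report
  expect_equal(rep$reason[rep$drug == "drug_a"], "single class")
  expect_match(rep$reason[rep$drug == "drug_b"], "class 1 has")
})
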