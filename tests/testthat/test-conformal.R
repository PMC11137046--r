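test_that("the modified calibration quantile uses the finite-sample
           order statistic with sentinels", {
  s <- runif(9)
  expect_equal(modified_quantile(s, 0.1), max(s))  # k = ceil(10*0.9) = 9
  expect_equal(modified_quantile(runif(3), 0.1), Inf)  # k = 4 > 3
  expect_equal(modified_quantile(c(0.1, 0.2, 0.5), 0.5), 0.2)  # k = 2
  expect_equal(modified_quantile(c(0.3, 0.1), 1), -Inf)  # k = 0
  expect_error(modified_quantile(numeric(0), 0.1), "empty")
  expect_error(modified_quantile(c(0.1, NA), 0.1), "finite")
})

test_that("True-class score and sets", {
  v <- matrix(c(0.7, 0.3), 1, dimnames = list(NULL, c("0", "1")))
  expect_equal(tc_score(v, 0), 0.3)
  expect_equal(tc_score(matrix(c(1, 0), 1,
                               dimnames = list(NULL, c("0", "1"))), 0), 0)
  expect_equal(tc_score(matrix(c(0, 1), 1,
                               dimnames = list(NULL, c("0", "1"))), 0), 1)
  expect_error(tc_score(v, 7), "unknown class")

  v2 <- matrix(c(0.8, 0.2), 1, dimnames = list(NULL, c("0", "1")))
  expect_equal(tc_set(v2, 0.3)[[1]], "0")          # scores 0.2, 0.8
  expect_equal(tc_set(v2, Inf)[[1]], c("0", "1"))  # sentinel: full set
  v5 <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("0", "1")))
  expect_length(tc_set(v5, 0.4)[[1]], 0)           # empty set permitted
})

test_that("Summation score and sets", {
  v <- matrix(c(0.3, 0.5, 0.2), 1, dimnames = list(NULL, c("1", "2", "3")))
  # descending order (2, 1, 3); true class second in the list -> 0.8
  expect_equal(sum_score(v, 1), 0.8)
  expect_equal(sum_score(v, 2), 0.5)  # top class: its own probability
  v1 <- matrix(c(1, 0, 0), 1, dimnames = list(NULL, c("1", "2", "3")))
  expect_equal(sum_score(v1, 1), 1)

  expect_equal(sum_set(v, 0.6)[[1]], c("1", "2"))  # top two
  expect_equal(sum_set(v, 0.4)[[1]], "2")          # empty sup -> top class
  expect_equal(sum_set(v, 1.0)[[1]], c("1", "2", "3"))
  # probability ties broken by ascending class code
  vt <- matrix(c(0.4, 0.4, 0.2), 1, dimnames = list(NULL, c("1", "2", "3")))
  expect_equal(sum_set(vt, 0.5)[[1]], c("1", "2"))
})

test_that("Mondrian calibration is per true class", {
  # identical per-class score distributions behave like global TC
  v <- rbind(diag(2)[rep(1:2, each = 10), ])
  v <- 0.8 * v + 0.1
  colnames(v) <- c("0", "1")
  lab <- rep(c(0, 1), each = 10)
  qm <- mondrian_calibrate(v, lab, alpha = 0.2)
  qg <- modified_quantile(tc_score(v, lab), 0.2)
  expect_equal(unname(qm), rep(qg, 2))

  # systematically worse minority scores -> larger minority threshold
  v2 <- rbind(matrix(c(0.9, 0.1), 20, 2, byrow = TRUE),
              matrix(c(0.45, 0.55), 6, 2, byrow = TRUE))
  colnames(v2) <- c("0", "1")
  lab2 <- rep(c(0, 1), c(20, 6))
  q2 <- mondrian_calibrate(v2, lab2, alpha = 0.2)
  expect_gt(q2[["1"]], q2[["0"]])

  # absent class -> Inf sentinel with warning, class always included
  expect_warning(q3 <- mondrian_calibrate(v2[1:20, ], lab2[1:20],
                                          alpha = 0.2,
                                          classes = c("0", "1")),
                 "absent")
  expect_equal(q3[["1"]], Inf)
  expect_true(all(vapply(mondrian_set(v2, q3), function(s) "1" %in% s,
                         logical(1))))
})

test_that("quantile score and interval conformalization are inverse", {
  expect_equal(quantile_score(2, 5, 6), 1)
  expect_equal(quantile_score(2, 5, 3), -1)
  expect_equal(quantile_score(2, 5, 5), 0)
  expect_error(quantile_score(5, 2, 3), "exceed")

  expect_equal(conformalize_interval(2, 5, 0),
               data.frame(lower = 2, upper = 5, degenerate = FALSE))
  expect_equal(conformalize_interval(2, 5, 0.5),
               data.frame(lower = 1.5, upper = 5.5, degenerate = FALSE))
  expect_true(conformalize_interval(2, 5, -2)$degenerate)

  # y inside the conformalized interval iff its score is <= q_hat
  set.seed(1)
  lo <- rnorm(200)
  hi <- lo + runif(200, 0, 2)
  y <- rnorm(200, sd = 2)
  for (qh in c(-0.3, 0, 0.7)) {
    iv <- conformalize_interval(lo, hi, qh)
    inside <- !iv$degenerate & y >= iv$lower & y <= iv$upper
    expect_equal(inside, quantile_score(lo, hi, y) <= qh)
  }
})

test_that("coverage reports count coverage, efficiency and relative
           width", {
  sets <- list("1", "0", "1")
  expect_equal(cp_evaluate(sets, c(1, 0, 1))$marginal_coverage, 1)
  expect_equal(cp_evaluate(sets, c(1, 0, 1))$efficiency, 1)
  full <- rep(list(c("0", "1")), 10)
  r <- cp_evaluate(full, rep(c(0, 1), 5))
  expect_equal(r$marginal_coverage, 1)
  expect_equal(r$efficiency, 0)
  iv <- data.frame(lower = 0:9, upper = 1:10, degenerate = FALSE)
  r2 <- cp_evaluate(iv, 0:9 + 0.5, training_range = c(0, 4))
  expect_equal(r2$mean_relative_width, 0.25)
  expect_equal(r2$marginal_coverage, 1)
  expect_error(cp_evaluate(list(), numeric(0)), "empty")
})

test_that("True-class sets shrink as alpha grows and Summation coverage
           dominates its full-set fraction on binary tasks", {
  set.seed(7)
  n <- 150
  p1 <- runif(n)
  votes <- cbind("0" = 1 - p1, "1" = p1)
  labels <- rbinom(n, 1, p1)
  idx_cal <- 1:75
  for (a2 in c(0.3, 0.5)) {
    a1 <- 0.1
    cb1 <- cp_calibrate(a1, "tc", votes = votes[idx_cal, ],
                        labels = labels[idx_cal])
    cb2 <- cp_calibrate(a2, "tc", votes = votes[idx_cal, ],
                        labels = labels[idx_cal])
    s1 <- cp_predict(cb1, votes = votes[-idx_cal, ])
    s2 <- cp_predict(cb2, votes = votes[-idx_cal, ])
    expect_true(all(mapply(function(a, b) all(b %in% a), s1, s2)))
  }
  cbs <- cp_calibrate(0.1, "sum", votes = votes[idx_cal, ],
                      labels = labels[idx_cal])
  ss <- cp_predict(cbs, votes = votes[-idx_cal, ])
  rep_s <- cp_evaluate(ss, labels[-idx_cal])
  expect_gte(rep_s$marginal_coverage, mean(lengths(ss) == 2))
})
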