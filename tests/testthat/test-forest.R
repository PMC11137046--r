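make_sim <- function(n = 120, p = 8, seed = 42, ...) {
  simulate_expression_response(n = n, p = p, n_informative = 4,
                               seed = seed, ...)
}

test_that("degenerate fits behave as documented", {
  # single sample: every tree is one leaf predicting y_1
  f1 <- suppressWarnings(
    sauron_rf(matrix(0, 1, 2), y = 3.5, d = 1, num_trees = 7,
              min_node_size = 1, seed = 1))
  pr <- predict(f1, matrix(rnorm(6), 3, 2))
  expect_equal(pr$value, rep(3.5, 3))

  # constant response: the forest predicts that constant everywhere
  x <- matrix(rnorm(60), 20, 3)
  fc <- sauron_rf(x, rep(2.25, 20), rep(c(0, 1), 10), num_trees = 11,
                  min_node_size = 2, seed = 1)
  expect_equal(predict(fc, matrix(rnorm(15), 5, 3))$value, rep(2.25, 5))

  expect_error(sauron_rf(matrix(0, 3, 1), 1:3, c(0, 1, 1),
                         min_node_size = 5), "min_node_size")
  expect_error(sauron_rf(matrix(c(1, Inf), 2, 1), 1:2, c(0, 1),
                         min_node_size = 1), "non-finite")
})

test_that("two separated clusters are split purely and training error
           vanishes", {
  x <- matrix(c(rnorm(25, -4), rnorm(25, 4)), ncol = 1)
  y <- rep(c(0, 10), each = 25)
  d <- rep(c(1, 0), each = 25)
  fit <- sauron_rf(x, y, d, num_trees = 20, min_node_size = 1, mtry = 1,
                   seed = 3)
  pr <- predict(fit, x)
  expect_lt(mean((pr$value - y)^2), 1e-12)
  expect_equal(pr$class, d)
  # every leaf is class-pure: its members share one label
  for (tr in fit$trees) {
    nl <- length(tr$leaf_pred)
    for (l in seq_len(nl)) {
      ids <- tr$leaf_members[(tr$leaf_ptr[l] + 1):tr$leaf_ptr[l + 1]] + 1L
      expect_length(unique(d[ids]), 1)
    }
  }
})

test_that("leaf aggregates match a direct evaluation of the weighted-leaf
           formulas", {
  sim <- make_sim(n = 60)
  fit <- sauron_rf(sim$x, sim$y, sim$d, weights = "simple", num_trees = 5,
                   min_node_size = 3, seed = 9)
  w_star <- fit$w_star
  didx <- match(fit$d, fit$classes)
  for (tr in fit$trees) {
    boot <- tr$boot_ids + 1L
    # recompute each leaf from the bootstrap multiset
    leaf_of_boot <- vapply(boot, function(i)
      tr$node_leaf[oracle_drop(tr, sim$x[i, ])] + 1L, numeric(1))
    for (l in seq_along(tr$leaf_pred)) {
      ids <- boot[leaf_of_boot == l]
      expect_gte(length(ids), fit$min_node_size)
      tot <- sum(w_star[ids])
      agg <- tapply(w_star[ids] / tot, ids, sum)  # duplicates collapsed
      sl <- (tr$leaf_ptr[l] + 1):tr$leaf_ptr[l + 1]
      expect_equal(tr$leaf_members[sl] + 1L, as.integer(names(agg)))
      expect_equal(tr$leaf_w[sl], as.numeric(agg), tolerance = 1e-12)
      expect_equal(tr$leaf_pred[l], sum(w_star[ids] * fit$y[ids]) / tot,
                   tolerance = 1e-12)
      # mode over bootstrap copies, ties to the lowest class index
      cnt <- tabulate(didx[ids], nbins = length(fit$classes))
      expect_equal(tr$leaf_mode[l], which.max(cnt))
    }
  }
})

test_that("tree_predict returns the normalized weighted leaf average", {
  # single-leaf trees with known content
  fit <- toy_forest(list(list(members = 0:1, w = c(0.5, 0.5), pred = 2,
                              mode = 1)),
                    y = c(1, 3), classes = c(0, 1), modal_class = 0)
  expect_equal(tree_predict(fit, 1, matrix(0, 1, 1)), 2)

  # w* = (1, 3), y = (0, 4): normalized weights (0.25, 0.75) -> 3
  x <- matrix(c(0, 0), 2, 1)
  f2 <- sauron_rf(x, y = c(0, 4), d = c(0, 1), weights = c(1, 3),
                  num_trees = 30, min_node_size = 1, seed = 2)
  # all features equal: every tree is a single leaf over its bootstrap;
  # find a tree whose bootstrap contains both samples once
  found <- FALSE
  for (b in seq_len(f2$num_trees)) {
    if (identical(sort(f2$trees[[b]]$boot_ids), c(0L, 1L))) {
      expect_equal(tree_predict(f2, b, x[1, , drop = FALSE]), 3)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("class-aware tree weighting follows the agreement rule", {
  y <- c(1, 2, 9)
  # three single-member leaves: two trees vote the minority class (index
  # 2), one votes the modal class -> minority weighting drops tree 3
  fit <- toy_forest(list(list(members = 0, w = 1, pred = 1, mode = 2),
                         list(members = 1, w = 1, pred = 2, mode = 2),
                         list(members = 2, w = 1, pred = 9, mode = 1)),
                    y = y, classes = c(0, 1), modal_class = 0)
  pr <- predict(fit, matrix(0, 1, 1))
  expect_equal(pr$class, 1)          # label of index 2
  expect_equal(pr$value, 1.5)        # mean of agreeing trees only
  expect_equal(as.numeric(pr$votes), c(1 / 3, 2 / 3))

  # when the modal class wins, every tree contributes 1/B
  fit2 <- toy_forest(list(list(members = 0, w = 1, pred = 1, mode = 1),
                          list(members = 1, w = 1, pred = 2, mode = 1),
                          list(members = 2, w = 1, pred = 9, mode = 2)),
                     y = y, classes = c(0, 1), modal_class = 0)
  pr2 <- predict(fit2, matrix(0, 1, 1))
  expect_equal(pr2$class, 0)
  expect_equal(pr2$value, mean(y))

  # 2-2 vote tie -> lowest class code wins
  fit3 <- toy_forest(list(list(members = 0, w = 1, pred = 1, mode = 1),
                          list(members = 1, w = 1, pred = 2, mode = 1),
                          list(members = 1, w = 1, pred = 2, mode = 2),
                          list(members = 2, w = 1, pred = 9, mode = 2)),
                     y = y, classes = c(0, 1), modal_class = 0)
  expect_equal(predict(fit3, matrix(0, 1, 1))$class, 0)
})

test_that("weight normalization and the two prediction forms agree", {
  for (seed in 1:3) {
    sim <- make_sim(n = 50, seed = seed)
    fit <- sauron_rf(sim$x, sim$y, sim$d, num_trees = 10,
                     min_node_size = 2, seed = seed)
    # per-leaf weights sum to 1
    for (tr in fit$trees)
      for (l in seq_along(tr$leaf_pred)) {
        sl <- (tr$leaf_ptr[l] + 1):tr$leaf_ptr[l + 1]
        expect_lt(abs(sum(tr$leaf_w[sl]) - 1), 1e-10)
      }
    xq <- matrix(rnorm(30 * ncol(sim$x)), 30)
    W <- forest_sample_weights(fit, xq)
    expect_true(all(abs(rowSums(W) - 1) < 1e-10))
    pr <- predict(fit, xq)
    expect_equal(as.numeric(W %*% fit$y), pr$value, tolerance = 1e-8)
  }
})

test_that("fits are reproducible for a fixed seed and leave the caller's
           RNG untouched", {
  sim <- make_sim(n = 60)
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  f1 <- sauron_rf(sim$x, sim$y, sim$d, num_trees = 8, seed = 11)
  expect_identical(rnorm(1), before)
  f2 <- sauron_rf(sim$x, sim$y, sim$d, num_trees = 8, seed = 11)
  xq <- sim$x[1:10, ]
  expect_identical(predict(f1, xq), predict(f2, xq))
  f3 <- sauron_rf(sim$x, sim$y, sim$d, num_trees = 8, seed = 12)
  expect_false(identical(predict(f1, xq)$value, predict(f3, xq)$value))
})

test_that("with balanced classes the simple scheme reduces to uniform
           weights, and predictions track a reference regression forest", {
  sim <- make_sim(n = 100, class_fractions = c(0.5, 0.5))
  f_simple <- sauron_rf(sim$x, sim$y, sim$d, weights = "simple",
                        num_trees = 25, seed = 5)
  f_unif <- sauron_rf(sim$x, sim$y, sim$d, weights = rep(1, 100),
                      num_trees = 25, seed = 5)
  xq <- sim$x[1:20, ]
  expect_equal(predict(f_simple, xq)$value, predict(f_unif, xq)$value)

  rf <- randomForest::randomForest(sim$x, sim$y, ntree = 200)
  ours <- predict(sauron_rf(sim$x, sim$y, sim$d, num_trees = 200,
                            seed = 5), sim$x)$value
  expect_gt(cor(ours, as.numeric(predict(rf, sim$x))), 0.9)
})

test_that("serialization round-trips bit-exactly", {
  sim <- make_sim(n = 60)
  fit <- sauron_rf(sim$x, sim$y, sim$d, weights = "simple", num_trees = 6,
                   seed = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_sauron(fit, path)
  back <- read_sauron(path)
  xq <- matrix(rnorm(20 * ncol(sim$x)), 20,
               dimnames = list(NULL, colnames(sim$x)))
  expect_identical(predict(fit, xq), predict(back, xq))
  expect_identical(predict_quantile(fit, xq, c(0.1, 0.9)),
                   predict_quantile(back, xq, c(0.1, 0.9)))
  expect_identical(back$y, fit$y)
  expect_identical(back$tree_seeds, fit$tree_seeds)
})
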