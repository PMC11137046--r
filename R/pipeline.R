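# End-to-end split conformal pipeline for one drug data set: train the
# forest, calibrate the requested scores, predict sets/intervals for the
# test samples, evaluate coverage.

#' Random train/calibration/test partition
#'
#' Partitions sample ids into the three disjoint sets required by split
#' conformal prediction.
#'
#' @param ids sample ids (or a single integer, interpreted as `1:n`).
#' @param fractions length-3 positive fractions summing to 1
#'   (train, calibration, test); default 70/15/15.
#' @param seed integer seed for the permutation.
#' @returns An object of class `split_spec`: a list with `train`, `cal`,
#'   `test` id vectors.
#' @examples
#' split_spec(100, seed = 1)
#' @export
split_spec <- function(ids, fractions = c(0.7, 0.15, 0.15), seed = NULL) {
  if (length(ids) == 1 && is.numeric(ids)) ids <- seq_len(ids)
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8, anyDuplicated(ids) == 0)
  n <- length(ids)
  n_train <- round(fractions[1] * n)
  n_cal <- round(fractions[2] * n)
  if (n_train < 1 || n_cal < 1 || n - n_train - n_cal < 1)
    stop("each split part must contain at least one sample")
  perm <- with_local_seed(seed, sample(ids))
  structure(list(train = perm[seq_len(n_train)],
                 cal = perm[n_train + seq_len(n_cal)],
                 test = perm[(n_train + n_cal + 1):n]),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("Split: train", length(x$train), "/ cal", length(x$cal), "/ test",
      length(x$test), "\n")
  invisible(x)
}

check_split <- function(split, ids) {
  stopifnot(inherits(split, "split_spec"))
  all_ids <- c(split$train, split$cal, split$test)
  if (anyDuplicated(all_ids) > 0)
    stop("train/calibration/test sets must be pairwise disjoint")
  if (!all(all_ids %in% ids))
    stop("split contains ids absent from the data")
  invisible(split)
}

#' Run the split conformal prediction pipeline on one drug data set
#'
#' Executes the four split-CP steps on a feature matrix with a continuous
#' and a discrete response: (1) fit a SAURON-RF forest on the training
#' part; (2/3) compute nonconformity scores on the calibration part and
#' derive the thresholds for each requested score function; (4) build
#' prediction sets and intervals for the test part and evaluate them.
#' The regression branch forms base intervals from the forest's
#' `alpha/2` and `1 - alpha/2` conditional quantiles and conformalizes
#' them with the Quantile score.
#'
#' @inheritParams sauron_rf
#' @param split a [split_spec()] over the rownames (or row indices) of
#'   `x`.
#' @param alpha maximal allowed error rate.
#' @param scores subset of `c("tc", "sum", "mondrian", "quantile")`.
#' @param ... further arguments passed to [sauron_rf()] (e.g. `num_trees`,
#'   `mtry`, `min_node_size`, `weights`, `seed`).
#' @returns A list with the fitted `model`, per-score `calibrators`,
#'   test-set `sets` / `intervals`, point predictions, and per-score
#'   coverage `reports`.
#' @examples
#' sim <- simulate_expression_response(n = 150, p = 10, seed = 7)
#' sp <- split_spec(rownames(sim$x), seed = 7)
#' res <- run_cp_pipeline(sim$x, sim$y, sim$d, sp, alpha = 0.1,
#'                        num_trees = 30, seed = 7)
#' res$reports$tc$marginal_coverage
#' @export
run_cp_pipeline <- function(x, y, d, split, alpha = 0.1,
                            scores = c("tc", "sum", "mondrian", "quantile"),
                            thresholds = NULL, ...) {
  x <- as_feature_matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- seq_len(nrow(x))
  rownames(x) <- ids
  names(y) <- names(d) <- ids
  check_split(split, ids)
  scores <- match.arg(scores, several.ok = TRUE)

  tr <- as.character(split$train)
  ca <- as.character(split$cal)
  te <- as.character(split$test)
  model <- sauron_rf(x[tr, , drop = FALSE], y[tr], d[tr],
                     thresholds = thresholds, ...)

  cal_pred <- predict(model, x[ca, , drop = FALSE])
  test_pred <- predict(model, x[te, , drop = FALSE])

  lv <- c(alpha / 2, 1 - alpha / 2)
  need_q <- "quantile" %in% scores
  cal_q <- if (need_q) predict_quantile(model, x[ca, , drop = FALSE], lv)
  test_q <- if (need_q) predict_quantile(model, x[te, , drop = FALSE], lv)

  calibrators <- list()
  sets <- list()
  intervals <- NULL
  reports <- list()
  for (sc in scores) {
    if (sc == "quantile") {
      cb <- cp_calibrate(alpha, "quantile", lower = cal_q[, 1],
                         upper = cal_q[, 2], y = y[ca])
      intervals <- cp_predict(cb, lower = test_q[, 1], upper = test_q[, 2])
      rownames(intervals) <- te
      reports[[sc]] <- cp_evaluate(intervals, y[te],
                                   training_range = range(y[tr]))
    } else {
      cb <- cp_calibrate(alpha, sc, votes = cal_pred$votes, labels = d[ca])
      sets[[sc]] <- setNames(cp_predict(cb, votes = test_pred$votes), te)
      reports[[sc]] <- cp_evaluate(sets[[sc]], d[te])
    }
    calibrators[[sc]] <- cb
  }

  list(model = model, alpha = alpha, split = split,
       calibrators = calibrators,
       point_class = setNames(test_pred$class, te),
       point_value = setNames(test_pred$value, te),
       votes = test_pred$votes, sets = sets, intervals = intervals,
       reports = reports,
       truth = list(d = d[te], y = y[te], train_range = range(y[tr])))
}
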