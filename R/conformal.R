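# Split conformal prediction on top of any model exposing class-vote
# proportions (classification) and/or quantile predictions (regression).
# All scores are oriented so that high values mean high uncertainty.

# comparison slack: scores on both sides of <= are computed from floating
# point vote proportions, so boundary cases need a deterministic tolerance
CP_EPS <- 1e-9

#' Finite-sample calibration quantile
#'
#' Returns the threshold \eqn{\hat q} used by split conformal prediction:
#' the k-th smallest calibration score with
#' \eqn{k = \lceil (N_{cal}+1)(1-\alpha) \rceil}.  The inflation by
#' \eqn{(N_{cal}+1)/N_{cal}} relative to the plain \eqn{(1-\alpha)}
#' quantile accounts for the finite calibration set and is what yields the
#' coverage guarantee.  When k exceeds the number of scores the sentinel
#' `Inf` is returned (prediction sets become the full label set, intervals
#' unbounded); when k is not positive, `-Inf`.
#'
#' @param scores numeric vector of calibration nonconformity scores.
#' @param alpha maximal allowed error rate in `[0, 1]`.
#' @returns A single numeric threshold (possibly `Inf` / `-Inf`).
#' @examples
#' modified_quantile(c(0.1, 0.2, 0.5), alpha = 0.5)  # 0.2
#' @export
modified_quantile <- function(scores, alpha) {
  if (length(scores) == 0) stop("empty score vector")
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite")
  stopifnot(alpha >= 0, alpha <= 1)
  n <- length(scores)
  # guard the ceiling against floating-point overshoot at exact integers
  lv <- (n + 1) * (1 - alpha)
  k <- ceiling(lv - 1e-8 * (n + 1))
  if (k > n) return(Inf)
  if (k <= 0) return(-Inf)
  sort(scores)[k]
}

check_votes <- function(votes, classes = NULL) {
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1,
                                           dimnames = list(NULL,
                                                           names(votes)))
  if (is.null(colnames(votes))) {
    if (is.null(classes))
      stop("'votes' needs class labels as column names")
    colnames(votes) <- as.character(classes)
  }
  if (any(abs(rowSums(votes) - 1) > 1e-6))
    stop("vote proportions must sum to 1 per sample")
  votes
}

label_col <- function(votes, label) {
  j <- match(as.character(label), colnames(votes))
  if (anyNA(j)) stop("unknown class label: ",
                     paste(label[is.na(j)], collapse = ", "))
  j
}

#' True-class nonconformity score
#'
#' The probability of misclassification under the model's vote
#' proportions: `1 - P(label | x)`.
#'
#' @param votes vote-proportion matrix (samples x classes, class labels as
#'   column names) or a single named vector.
#' @param label class label(s); a scalar or one label per row.
#' @returns Numeric score vector.
#' @export
tc_score <- function(votes, label) {
  votes <- check_votes(votes)
  j <- label_col(votes, label)
  if (length(j) == 1) j <- rep(j, nrow(votes))
  1 - votes[cbind(seq_len(nrow(votes)), j)]
}

#' True-class prediction set
#'
#' All classes whose True-class score is at most the calibrated threshold.
#' The set may be empty (an extremely unusual sample) and equals the full
#' label set when `q_hat` is the `Inf` sentinel.
#'
#' @inheritParams tc_score
#' @param q_hat calibrated threshold from [modified_quantile()].
#' @returns A list with one vector of class labels per row of `votes`.
#' @export
tc_set <- function(votes, q_hat) {
  votes <- check_votes(votes)
  labels <- colnames(votes)
  apply(votes, 1, function(p) labels[1 - p <= q_hat + CP_EPS],
        simplify = FALSE)
}

sorted_desc <- function(p) {
  # descending probability, ties broken by ascending class code
  order(-p, seq_along(p))
}

#' Summation (adaptive) nonconformity score
#'
#' Sorts the vote proportions in descending order (probability ties broken
#' by ascending class code) and accumulates them up to and including the
#' true class.
#'
#' @inheritParams tc_score
#' @returns Numeric score vector.
#' @export
sum_score <- function(votes, label) {
  votes <- check_votes(votes)
  j <- label_col(votes, label)
  if (length(j) == 1) j <- rep(j, nrow(votes))
  vapply(seq_len(nrow(votes)), function(i) {
    ord <- sorted_desc(votes[i, ])
    sum(votes[i, ord[seq_len(match(j[i], ord))]])
  }, numeric(1))
}

#' Summation prediction set
#'
#' Includes the top classes of the descending-sorted vote list until their
#' cumulative probability reaches the calibrated threshold; the set always
#' contains at least the top-voted class.
#'
#' @inheritParams tc_set
#' @returns A list with one vector of class labels per row of `votes`.
#' @export
sum_set <- function(votes, q_hat) {
  votes <- check_votes(votes)
  labels <- colnames(votes)
  k <- ncol(votes)
  apply(votes, 1, function(p) {
    ord <- sorted_desc(p)
    cum <- cumsum(p[ord])
    m <- min(sum(cum < q_hat - CP_EPS) + 1L, k)
    labels[sort(ord[seq_len(m)])]
  }, simplify = FALSE)
}

#' Per-class Mondrian calibration
#'
#' Class-conditional conformal calibration with the True-class base score:
#' the calibration scores are split by true class and a separate
#' [modified_quantile()] threshold is computed per class, which yields the
#' per-true-class coverage guarantee.  Classes absent from the calibration
#' set receive the `Inf` sentinel (always included) with a warning.
#'
#' @param votes calibration vote-proportion matrix.
#' @param labels true class labels of the calibration samples.
#' @param alpha maximal allowed error rate.
#' @param classes full set of class labels; defaults to the columns of
#'   `votes`.
#' @returns Named numeric vector of per-class thresholds \eqn{\hat q^l}.
#' @export
mondrian_calibrate <- function(votes, labels, alpha, classes = NULL) {
  votes <- check_votes(votes, classes)
  if (is.null(classes)) classes <- colnames(votes)
  classes <- as.character(classes)
  scores <- tc_score(votes, labels)
  q <- vapply(classes, function(cl) {
    sel <- as.character(labels) == cl
    if (!any(sel)) {
      warning("class ", cl, " absent from calibration data; ",
              "it will always be included")
      return(Inf)
    }
    modified_quantile(scores[sel], alpha)
  }, numeric(1))
  q
}

#' Mondrian prediction set
#'
#' @inheritParams tc_set
#' @param q_hat named vector of per-class thresholds from
#'   [mondrian_calibrate()].
#' @returns A list with one vector of class labels per row of `votes`.
#' @export
mondrian_set <- function(votes, q_hat) {
  votes <- check_votes(votes)
  labels <- colnames(votes)
  q <- q_hat[labels]
  apply(votes, 1, function(p) labels[1 - p <= q + CP_EPS],
        simplify = FALSE)
}

#' Quantile (conformalized quantile regression) score
#'
#' Signed distance between the response and the nearest boundary of the
#' base quantile interval: negative inside, positive outside, zero on a
#' boundary.
#'
#' @param lower,upper base interval boundaries (lower/upper quantile
#'   predictions).
#' @param y observed responses.
#' @returns Numeric score vector `max(lower - y, y - upper)`.
#' @export
quantile_score <- function(lower, upper, y) {
  if (any(lower > upper)) stop("'lower' must not exceed 'upper'")
  pmax(lower - y, y - upper)
}

#' Conformalize a quantile interval
#'
#' Widens (`q_hat > 0`) or narrows (`q_hat < 0`) the base interval by the
#' calibrated threshold.  When the narrowing exceeds the interval width the
#' result is degenerate (empty) and flagged.
#'
#' @inheritParams quantile_score
#' @param q_hat calibrated threshold.
#' @returns A data frame with columns `lower`, `upper`, `degenerate`.
#' @export
conformalize_interval <- function(lower, upper, q_hat) {
  if (any(lower > upper)) stop("'lower' must not exceed 'upper'")
  data.frame(lower = lower - q_hat, upper = upper + q_hat,
             degenerate = (upper - lower) + 2 * q_hat < 0)
}

#' Calibrate a conformal predictor
#'
#' Step 3 of the split conformal procedure: apply the trained model to the
#' calibration set, compute nonconformity scores, and derive the
#' threshold(s) \eqn{\hat q} for the requested error rate.
#'
#' @param alpha maximal allowed error rate in `[0, 1]`.
#' @param score one of `"tc"` (True-class), `"sum"` (Summation),
#'   `"mondrian"` (class-conditional True-class), `"quantile"`
#'   (conformalized quantile regression).
#' @param votes calibration vote-proportion matrix (classification scores).
#' @param labels true calibration class labels (classification scores).
#' @param lower,upper base quantile interval on the calibration set
#'   (quantile score).
#' @param y true calibration responses (quantile score).
#' @param classes optional full label set (defaults to `colnames(votes)`).
#' @returns An object of class `conformal_calibrator` carrying the score
#'   kind, `alpha`, the calibration scores and the threshold(s).
#' @seealso [cp_predict()], [cp_evaluate()]
#' @export
cp_calibrate <- function(alpha, score = c("tc", "sum", "mondrian",
                                          "quantile"),
                         votes = NULL, labels = NULL,
                         lower = NULL, upper = NULL, y = NULL,
                         classes = NULL) {
  score <- match.arg(score)
  stopifnot(alpha >= 0, alpha <= 1)
  if (score == "quantile") {
    stopifnot(!is.null(lower), !is.null(upper), !is.null(y))
    cal_scores <- quantile_score(lower, upper, y)
    q_hat <- modified_quantile(cal_scores, alpha)
  } else {
    stopifnot(!is.null(votes), !is.null(labels))
    votes <- check_votes(votes, classes)
    if (score == "mondrian") {
      cal_scores <- tc_score(votes, labels)
      q_hat <- mondrian_calibrate(votes, labels, alpha, classes)
    } else {
      cal_scores <- switch(score, tc = tc_score(votes, labels),
                           sum = sum_score(votes, labels))
      q_hat <- modified_quantile(cal_scores, alpha)
    }
    classes <- colnames(votes)
  }
  structure(list(score = score, alpha = alpha, q_hat = q_hat,
                 cal_scores = cal_scores, n_cal = length(cal_scores),
                 classes = classes),
            class = "conformal_calibrator")
}

#' @export
print.conformal_calibrator <- function(x, ...) {
  cat("Conformal calibrator:", x$score, "score, alpha =", x$alpha,
      ", n_cal =", x$n_cal, "\n")
  cat("  q_hat:", paste(signif(x$q_hat, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Conformal prediction sets or intervals for new samples
#'
#' Step 4 of the split conformal procedure: combines the calibrated
#' threshold with the model output for test samples.
#'
#' @param calibrator a [cp_calibrate()] object.
#' @param votes test vote-proportion matrix (classification scores).
#' @param lower,upper base quantile interval for the test samples
#'   (quantile score).
#' @returns Classification: a list of label vectors (one prediction set
#'   per sample).  Regression: a data frame from
#'   [conformalize_interval()].
#' @export
cp_predict <- function(calibrator, votes = NULL, lower = NULL,
                       upper = NULL) {
  stopifnot(inherits(calibrator, "conformal_calibrator"))
  switch(calibrator$score,
         tc = tc_set(check_votes(votes, calibrator$classes),
                     calibrator$q_hat),
         sum = sum_set(check_votes(votes, calibrator$classes),
                       calibrator$q_hat),
         mondrian = mondrian_set(check_votes(votes, calibrator$classes),
                                 calibrator$q_hat),
         quantile = conformalize_interval(lower, upper, calibrator$q_hat))
}

#' Coverage and efficiency diagnostics
#'
#' Evaluates conformal outputs against known truths.  For classification
#' (`pred` a list of label sets): marginal coverage, per-true-class
#' coverage, and efficiency (the fraction of single-class sets).  For
#' regression (`pred` a data frame of intervals): marginal coverage and
#' the mean interval width relative to the spanned training response
#' range.
#'
#' @param pred prediction sets (list) or intervals (data frame with
#'   `lower`/`upper`).
#' @param truth true class labels or responses, one per prediction.
#' @param training_range numeric range of the training responses (used to
#'   normalize interval widths).
#' @returns A list of class `coverage_report`.
#' @export
cp_evaluate <- function(pred, truth, training_range = NULL) {
  if (length(truth) == 0) stop("empty input")
  if (is.data.frame(pred)) {
    stopifnot(nrow(pred) == length(truth))
    covered <- !pred$degenerate & truth >= pred$lower - CP_EPS &
      truth <= pred$upper + CP_EPS
    width <- pmax(pred$upper - pred$lower, 0)
    rel <- if (is.null(training_range)) NA_real_
    else mean(width) / abs(diff(range(training_range)))
    out <- list(task = "regression", marginal_coverage = mean(covered),
                mean_width = mean(width), mean_relative_width = rel,
                n = length(truth))
  } else {
    stopifnot(is.list(pred), length(pred) == length(truth))
    truth <- as.character(truth)
    covered <- mapply(function(s, tr) tr %in% as.character(s), pred, truth)
    per_class <- tapply(covered, truth, mean)
    out <- list(task = "classification",
                marginal_coverage = mean(covered),
                per_class_coverage = per_class,
                efficiency = mean(lengths(pred) == 1L),
                mean_set_size = mean(lengths(pred)), n = length(truth))
  }
  structure(out, class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage report (", x$task, ", n = ", x$n, ")\n", sep = "")
  cat("  marginal coverage:", round(x$marginal_coverage, 4), "\n")
  if (x$task == "classification") {
    cat("  per-class coverage:",
        paste(names(x$per_class_coverage),
              round(x$per_class_coverage, 4), sep = "=", collapse = ", "),
        "\n")
    cat("  efficiency (singleton sets):", round(x$efficiency, 4), "\n")
  } else {
    cat("  mean width:", signif(x$mean_width, 5),
        " relative:", signif(x$mean_relative_width, 5), "\n")
  }
  invisible(x)
}
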