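# Confusion-matrix and association metrics used throughout the
# evaluation.  Undefined quantities (zero denominators, constant vectors)
# are reported as NA, never silently as 0.

#' Confusion-matrix metrics
#'
#' Counts TP/FP/TN/FN against a designated positive class and derives
#' sensitivity = TP/(TP+FN), miss-rate = FN/(TP+FN),
#' specificity = TN/(TN+FP), and fall-out = FP/(TN+FP).  Rates with a zero
#' denominator are `NA`.
#'
#' @param truth,pred equal-length label vectors.
#' @param positive the class treated as positive (e.g. sensitive = 1).
#' @param labels optional label universe; values outside it raise an
#'   error.
#' @returns A list of counts and rates of class `confusion_summary`.
#' @examples
#' confusion_metrics(c(1, 1, 1, 1, 0), c(1, 1, 1, 0, 0), positive = 1)
#' @export
confusion_metrics <- function(truth, pred, positive, labels = NULL) {
  stopifnot(length(truth) == length(pred))
  if (!is.null(labels)) {
    bad <- setdiff(unique(c(truth, pred)), labels)
    if (length(bad))
      stop("label(s) outside the class scheme: ",
           paste(bad, collapse = ", "))
  }
  tpos <- truth == positive
  ppos <- pred == positive
  tp <- sum(tpos & ppos)
  fn <- sum(tpos & !ppos)
  tn <- sum(!tpos & !ppos)
  fp <- sum(!tpos & ppos)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = rate(tp, tp + fn),
                 miss_rate = rate(fn, tp + fn),
                 specificity = rate(tn, tn + fp),
                 fall_out = rate(fp, tn + fp)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("TP", x$TP, " FP", x$FP, " TN", x$TN, " FN", x$FN, "\n")
  cat("sensitivity", signif(x$sensitivity, 4),
      " specificity", signif(x$specificity, 4),
      " miss-rate", signif(x$miss_rate, 4),
      " fall-out", signif(x$fall_out, 4), "\n")
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' Binary and multi-class (generalized, k x k) MCC.  Returns `NA` when a
#' marginal is degenerate (the denominator vanishes).
#'
#' @param truth,pred equal-length label vectors.
#' @returns MCC in `[-1, 1]` or `NA`.
#' @export
mcc <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  lev <- sort(unique(c(truth, pred)))
  tt <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  s <- sum(tt)
  c_ok <- sum(diag(tt))
  t_k <- rowSums(tt)  # true counts
  p_k <- colSums(tt)  # predicted counts
  num <- c_ok * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Association metrics between truth and predictions
#'
#' Mean-squared error, Pearson and Spearman correlations on the continuous
#' values, and (when label vectors are supplied) the Matthews correlation
#' coefficient on the discrete labels.  Correlations of constant vectors
#' are `NA`.
#'
#' @param y_true,y_pred continuous truth/prediction vectors.
#' @param d_true,d_pred optional discrete label vectors for the MCC.
#' @returns A list with `MSE`, `PCC`, `SCC`, and `MCC` (`NA` if labels are
#'   not given).
#' @export
association_metrics <- function(y_true, y_pred, d_true = NULL,
                                d_pred = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  safe_cor <- function(method)
    if (sd(y_true) == 0 || sd(y_pred) == 0) NA_real_
  else cor(y_true, y_pred, method = method)
  list(MSE = mean((y_true - y_pred)^2),
       PCC = safe_cor("pearson"),
       SCC = safe_cor("spearman"),
       MCC = if (is.null(d_true)) NA_real_ else mcc(d_true, d_pred))
}
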