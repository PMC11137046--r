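#' Bundle a continuous and a discrete drug response
#'
#' A response bundle ties together the continuous response `y` (for example
#' log-IC50 values or CMax viabilities), the discrete class labels `d`
#' derived from it, and, optionally, the discretization thresholds that
#' relate the two.  Class codes follow the package conventions: binary
#' responses use resistant = 0 / sensitive = 1, ternary responses use
#' sensitive = 1, ambiguous = 2, resistant = 3, but any integer coding is
#' accepted.
#'
#' When `thresholds` are supplied, the classes are ordered along the
#' response axis (by their median `y`) and each sample is checked to lie
#' within its class band, up to boundary ties.  Labels that were produced
#' by an upstream process other than thresholding `y` (e.g. labels defined
#' on a latent noiseless signal) should be bundled without thresholds.
#'
#' @param y numeric vector, continuous response.
#' @param d vector of class labels, same length as `y`.
#' @param thresholds optional numeric vector of k-1 ascending thresholds on
#'   the scale of `y`.
#' @returns An object of class `response_bundle` with elements `y`, `d`,
#'   `classes` (sorted class codes), `counts`, `modal_class` (relative
#'   majority; ties broken towards the lowest code), `thresholds`, and
#'   `band_order` (classes in ascending-response order, when thresholds are
#'   given).
#' @examples
#' b <- response_bundle(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0),
#'                      thresholds = 0.5)
#' b$modal_class
#' @export
response_bundle <- function(y, d, thresholds = NULL) {
  stopifnot(is.numeric(y), length(y) == length(d), length(y) >= 1)
  if (anyNA(y) || any(!is.finite(y))) stop("'y' contains non-finite values")
  if (anyNA(d)) stop("'d' contains missing values")
  classes <- sort(unique(d))
  counts <- as.integer(table(factor(d, levels = classes)))
  names(counts) <- as.character(classes)
  modal_class <- classes[which.max(counts)]  # ties -> lowest code
  band_order <- NULL
  if (!is.null(thresholds)) {
    k <- length(classes)
    if (length(thresholds) != k - 1L)
      stop("expected ", k - 1L, " thresholds for ", k, " classes")
    if (is.unsorted(thresholds, strictly = TRUE))
      stop("'thresholds' must be strictly increasing")
    med <- vapply(classes, function(cl) median(y[d == cl]), numeric(1))
    band_order <- classes[order(med)]
    tol <- 1e-8 * max(1, diff(range(y)))
    lo <- c(-Inf, thresholds)
    hi <- c(thresholds, Inf)
    for (j in seq_len(k)) {
      yy <- y[d == band_order[j]]
      if (any(yy < lo[j] - tol) || any(yy > hi[j] + tol))
        stop("labels are inconsistent with thresholding 'y': class ",
             band_order[j], " has samples outside (",
             signif(lo[j], 4), ", ", signif(hi[j], 4), "]")
    }
  }
  structure(list(y = y, d = d, classes = classes, counts = counts,
                 modal_class = modal_class, thresholds = thresholds,
                 band_order = band_order),
            class = "response_bundle")
}

#' @export
print.response_bundle <- function(x, ...) {
  cat("Response bundle:", length(x$y), "samples,",
      length(x$classes), "classes\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "),
      " modal:", x$modal_class, "\n")
  if (!is.null(x$thresholds))
    cat("  thresholds:", paste(signif(x$thresholds, 4), collapse = ", "),
        "\n")
  invisible(x)
}

#' Class-imbalance sample weights for SAURON-RF
#'
#' Computes the per-sample weights \eqn{w_i^*} that counteract class
#' imbalance during forest training.  Three schemes are available:
#'
#' * `"simple"`: samples of the modal (relative-majority) class get weight
#'   1; samples of any other class \eqn{c_j} get \eqn{N_{mode}/N_{c_j}}.
#' * `"linear"` / `"quadratic"`: weights proportional to the distance
#'   \eqn{|y_i - t|^g} (g = 1 or 2) from the discretization threshold(s),
#'   normalized within each class so that every class carries total weight
#'   \eqn{1/k}.  Interior classes of a multi-class scheme average the
#'   distances to their two bounding thresholds.
#'
#' @param bundle a [response_bundle()]; the distance schemes require its
#'   `thresholds`.
#' @param scheme one of `"simple"`, `"linear"`, `"quadratic"`.
#' @param g distance exponent, 1 (linear) or 2 (quadratic); ignored for the
#'   simple scheme.
#' @returns Numeric vector of weights with attributes `scheme` and `g`.
#'   Samples lying exactly on their only threshold receive weight 0 under a
#'   distance scheme (with a warning).
#' @examples
#' b <- response_bundle(c(1, 2, 3, 4, 10), c(0, 0, 0, 0, 1))
#' compute_sample_weights(b, "simple")  # 1 1 1 1 4
#' @export
compute_sample_weights <- function(bundle,
                                   scheme = c("simple", "linear",
                                              "quadratic"),
                                   g = NULL) {
  stopifnot(inherits(bundle, "response_bundle"))
  scheme <- match.arg(scheme)
  k <- length(bundle$classes)
  n <- length(bundle$y)
  if (scheme == "simple") {
    if (k < 2)
      stop("simple weighting needs at least two classes ",
           "(all samples belong to one class)")
    w <- bundle$counts[[as.character(bundle$modal_class)]] /
      bundle$counts[as.character(bundle$d)]
    w <- unname(w)
  } else {
    g <- if (is.null(g)) switch(scheme, linear = 1, quadratic = 2) else g
    if (!g %in% c(1, 2)) stop("'g' must be 1 or 2")
    if (is.null(bundle$thresholds))
      stop("distance-based weights require thresholds in the bundle")
    thr <- bundle$thresholds
    bands <- bundle$band_order
    dist <- numeric(n)
    for (j in seq_len(k)) {
      sel <- bundle$d == bands[j]
      if (j == 1L) {
        dist[sel] <- abs(bundle$y[sel] - thr[1L])^g
      } else if (j == k) {
        dist[sel] <- abs(bundle$y[sel] - thr[k - 1L])^g
      } else {
        dist[sel] <- abs(bundle$y[sel] - thr[j - 1L])^g +
          abs(bundle$y[sel] - thr[j])^g
      }
    }
    w <- numeric(n)
    for (cl in bundle$classes) {
      sel <- bundle$d == cl
      denom <- k * sum(dist[sel])
      if (denom == 0)
        stop("all samples of class ", cl, " lie exactly on a threshold; ",
             "distance weights are undefined")
      w[sel] <- dist[sel] / denom
    }
    if (any(w == 0))
      warning(sum(w == 0), " sample(s) lie exactly on a threshold and ",
              "receive weight 0")
  }
  structure(w, scheme = scheme, g = if (scheme == "simple") NA_real_ else g)
}
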