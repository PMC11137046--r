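# CMax viability: intersect a fitted dose-response curve with the vertical
# line at the drug's peak plasma concentration (CMax), then discretize the
# pooled viabilities across drugs with 1-D k-medoids (PAM).

#' Fit a monotone sigmoid dose-response curve
#'
#' Least-squares fit of a two-parameter logistic on the log-concentration
#' scale, \deqn{v(c) = 1 / (1 + \exp(s \cdot (\log c - m)))}{
#' v(c) = 1 / (1 + exp(s (log c - m)))}, with midpoint `m` (log µM) and
#' slope `s >= 0`, so the predicted viability decreases monotonically from
#' 1 towards 0.  Fitting uses Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]) started from a small grid of midpoint/slope
#' values; the best converged fit wins.  Dose-response points whose
#' viabilities are essentially constant are represented by a flat curve at
#' their mean (clipped to `[0, 1]`).
#'
#' @param concentration positive drug concentrations (µM); replicates
#'   allowed.
#' @param viability viabilities as fractions of the untreated control
#'   (noise may push individual points slightly outside `[0, 1]`).
#' @returns An object of class `dose_response_fit` with elements `kind`
#'   (`"logistic2"` or `"constant"`), `params`, `conc_range`, `rss`, `n`.
#' @examples
#' conc <- 10^seq(-3, 1, length.out = 9)
#' viab <- 1 / (1 + exp(1.2 * (log(conc) - log(0.1))))
#' fit <- fit_dose_response(conc, viab)
#' predict(fit, 0.1)  # ~0.5 at the midpoint
#' @export
fit_dose_response <- function(concentration, viability) {
  stopifnot(length(concentration) == length(viability))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be positive and finite")
  if (any(!is.finite(viability))) stop("viabilities must be finite")
  if (length(unique(concentration)) < 3)
    stop("at least 3 distinct concentrations are required")
  lc <- log(concentration)
  cr <- range(concentration)

  if (diff(range(viability)) < 1e-8) {
    return(structure(list(kind = "constant",
                          params = c(value = min(max(mean(viability), 0),
                                                 1)),
                          conc_range = cr, rss = 0,
                          n = length(viability)),
                     class = "dose_response_fit"))
  }

  dat <- data.frame(lc = lc, v = viability)
  best <- NULL
  starts <- expand.grid(m = seq(min(lc), max(lc), length.out = 5),
                        s = c(0.5, 1, 2, 4))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ 1 / (1 + exp(s * (lc - m))), data = dat,
                        start = list(m = starts$m[i], s = starts$s[i]),
                        lower = c(m = -Inf, s = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("dose-response fit did not converge for any start ",
         "(n = ", length(viability), ", viability range = ",
         paste(signif(range(viability), 3), collapse = ".."), ")")
  p <- coef(best$fit)
  structure(list(kind = "logistic2",
                 params = c(m = unname(p["m"]), s = unname(p["s"])),
                 conc_range = cr, rss = best$rss, n = length(viability)),
            class = "dose_response_fit")
}

#' Evaluate a fitted dose-response curve
#'
#' @param object a [fit_dose_response()] fit.
#' @param concentration positive concentrations (µM).
#' @param ... unused.
#' @returns Predicted viabilities clipped to `[0, 1]`, with a logical
#'   attribute `extrapolated` flagging concentrations outside the fitted
#'   range.
#' @export
predict.dose_response_fit <- function(object, concentration, ...) {
  stopifnot(all(concentration > 0))
  v <- switch(object$kind,
              constant = rep(object$params[["value"]],
                             length(concentration)),
              logistic2 = 1 / (1 + exp(object$params[["s"]] *
                                       (log(concentration) -
                                        object$params[["m"]]))))
  v <- pmin(pmax(v, 0), 1)
  attr(v, "extrapolated") <- concentration < object$conc_range[1] |
    concentration > object$conc_range[2]
  v
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit (", x$kind, "), ", x$n, " points, rss = ",
      signif(x$rss, 4), "\n", sep = "")
  cat("  params:", paste(names(x$params), signif(x$params, 5), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' CMax viability of one drug/cell-line combination
#'
#' Evaluates the fitted dose-response curve at the drug's CMax
#' concentration (the peak plasma concentration at the highest clinically
#' recommended dose).  The value lies in `[0, 1]`; 0 means no viable cells
#' at the clinically achievable dose, 1 means the drug does not reduce
#' viability at all.
#'
#' @param curve a [fit_dose_response()] fit.
#' @param cmax positive CMax concentration (µM).
#' @returns A list with `value` (clipped to `[0, 1]`) and `extrapolated`
#'   (`TRUE` when CMax lies outside the tested concentration range).
#' @export
cmax_viability <- function(curve, cmax) {
  stopifnot(inherits(curve, "dose_response_fit"), length(cmax) == 1,
            cmax > 0)
  v <- predict(curve, cmax)
  list(value = as.numeric(v), extrapolated = attr(v, "extrapolated")[1])
}

#' CMax-viability matrix for a dose-response panel
#'
#' Fits one dose-response curve per drug/cell-line combination and
#' evaluates it at the drug's CMax concentration.
#'
#' @param points data frame with columns `drug`, `cell_line`,
#'   `concentration_uM`, `viability` (replicates allowed).
#' @param cmax_table data frame with columns `drug`, `cmax_uM`.
#' @returns A list with `values` (cell lines x drugs matrix in `[0, 1]`,
#'   `NA` for combinations that could not be fitted), `extrapolated`
#'   (logical matrix), and `failures` (data frame of failed fits).
#' @export
cmax_viability_matrix <- function(points, cmax_table) {
  need <- c("drug", "cell_line", "concentration_uM", "viability")
  stopifnot(all(need %in% names(points)),
            all(c("drug", "cmax_uM") %in% names(cmax_table)))
  drugs <- unique(as.character(points$drug))
  cells <- unique(as.character(points$cell_line))
  cmax <- setNames(cmax_table$cmax_uM, as.character(cmax_table$drug))
  if (!all(drugs %in% names(cmax)))
    stop("missing CMax concentrations for: ",
         paste(setdiff(drugs, names(cmax)), collapse = ", "))
  vals <- matrix(NA_real_, length(cells), length(drugs),
                 dimnames = list(cells, drugs))
  extr <- matrix(NA, length(cells), length(drugs),
                 dimnames = list(cells, drugs))
  fails <- list()
  for (dr in drugs) {
    sub <- points[points$drug == dr, ]
    for (cl in unique(as.character(sub$cell_line))) {
      pp <- sub[sub$cell_line == cl, ]
      res <- tryCatch({
        cv <- cmax_viability(fit_dose_response(pp$concentration_uM,
                                               pp$viability), cmax[[dr]])
        vals[cl, dr] <- cv$value
        extr[cl, dr] <- cv$extrapolated
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        fails[[length(fails) + 1L]] <- data.frame(drug = dr,
                                                  cell_line = cl,
                                                  reason = res)
    }
  }
  list(values = vals, extrapolated = extr,
       failures = if (length(fails)) do.call(rbind, fails)
       else data.frame(drug = character(), cell_line = character(),
                       reason = character()))
}

#' Across-drug discretization of CMax viabilities with PAM
#'
#' Clusters the pooled CMax viabilities of *all* drugs with 1-D k-medoids
#' (partitioning around medoids), producing `k - 1` thresholds valid for
#' every drug.  Thresholds are the midpoints between the boundary points
#' of adjacent clusters (the maximum of the lower cluster and the minimum
#' of the upper one); midpoints between adjacent medoids are available as
#' an alternative.  The cluster with the lowest viability is the sensitive
#' class.
#'
#' @param values pooled CMax viabilities across all drugs (`NA` dropped).
#' @param k number of classes, 2 or 3.
#' @param midpoint `"boundary"` (default) or `"medoid"`.
#' @returns An object of class `discretization_model` with `k`, sorted
#'   `medoids`, `thresholds`, and `band_labels` (class codes in ascending
#'   viability order: `c(1, 0)` for binary sensitive/resistant,
#'   `c(1, 2, 3)` for ternary).
#' @examples
#' m <- pam_discretize(c(0.05, 0.1, 0.15, 0.85, 0.9, 0.95), k = 2)
#' m$thresholds  # 0.5
#' @export
pam_discretize <- function(values, k = 2,
                           midpoint = c("boundary", "medoid")) {
  midpoint <- match.arg(midpoint)
  stopifnot(k %in% c(2, 3))
  values <- values[!is.na(values)]
  if (length(unique(values)) < k)
    stop("need at least ", k, " distinct values for ", k, " clusters")
  pm <- cluster::pam(matrix(values, ncol = 1), k = k, cluster.only = FALSE)
  med <- sort(as.numeric(pm$medoids))
  grp <- findInterval(values, vapply(seq_len(k - 1), function(j) {
    (med[j] + med[j + 1]) / 2  # nearest-medoid boundary in 1-D
  }, numeric(1))) + 1L
  thresholds <- vapply(seq_len(k - 1), function(j) {
    if (midpoint == "medoid") (med[j] + med[j + 1]) / 2
    else (max(values[grp == j]) + min(values[grp == j + 1])) / 2
  }, numeric(1))
  band_labels <- if (k == 2) c(1, 0) else c(1, 2, 3)
  structure(list(k = k, medoids = med, thresholds = thresholds,
                 midpoint = midpoint, band_labels = band_labels),
            class = "discretization_model")
}

#' @export
print.discretization_model <- function(x, ...) {
  cat("PAM discretization: k =", x$k, "\n")
  cat("  medoids:", paste(signif(x$medoids, 5), collapse = ", "), "\n")
  cat("  thresholds (", x$midpoint, "):",
      paste(signif(x$thresholds, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Apply discretization thresholds to viabilities
#'
#' Maps continuous CMax viabilities to class labels: binary sensitive (1)
#' below the threshold / resistant (0) above; ternary sensitive (1),
#' ambiguous (2), resistant (3) in ascending viability bands.  Values
#' lying exactly on a threshold are assigned to the lower-viability (more
#' sensitive) class.
#'
#' @param values numeric viabilities (`NA` passed through).
#' @param model a [pam_discretize()] model (or any list with `thresholds`
#'   and `band_labels`).
#' @returns Vector of class labels.
#' @export
apply_thresholds <- function(values, model) {
  thr <- model$thresholds
  band <- rowSums(outer(values, thr, `>`)) + 1L
  model$band_labels[band]
}

#' Drop drugs that cannot be analyzed
#'
#' A drug is retained only if its discretized responses contain more than
#' one class and every present class has at least `min_per_class` samples
#' in each of the train, calibration and test parts; otherwise imbalance
#' makes training or per-class calibration meaningless.
#'
#' @param labels cell lines x drugs matrix (or data frame) of discrete
#'   labels; `NA` marks missing measurements.
#' @param split a [split_spec()] over the rownames of `labels`.
#' @param min_per_class minimum samples per present class and split part.
#' @returns A list with `retained` (drug names) and `report` (data frame
#'   with a `reason` per dropped drug).
#' @export
filter_analyzable_drugs <- function(labels, split, min_per_class = 3) {
  labels <- as.matrix(labels)
  check_split(split, rownames(labels))
  parts <- list(train = split$train, cal = split$cal, test = split$test)
  rep_rows <- lapply(colnames(labels), function(dr) {
    lab <- labels[, dr]
    present <- sort(unique(lab[!is.na(lab)]))
    if (length(present) < 2)
      return(data.frame(drug = dr, kept = FALSE, reason = "single class"))
    for (pn in names(parts)) {
      cnt <- table(factor(lab[as.character(parts[[pn]])],
                          levels = present))
      if (any(cnt < min_per_class))
        return(data.frame(drug = dr, kept = FALSE,
                          reason = sprintf(
                            "class %s has %d < %d samples in %s",
                            names(cnt)[which.min(cnt)], min(cnt),
                            min_per_class, pn)))
    }
    data.frame(drug = dr, kept = TRUE, reason = "")
  })
  report <- do.call(rbind, rep_rows)
  list(retained = report$drug[report$kept], report = report)
}
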