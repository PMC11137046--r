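# Seeded generators emulating the three kinds of input the pipeline
# consumes: expression-like feature matrices with continuous + discrete
# responses, raw dose-response panels with known CMax viabilities, and
# multi-drug panels sharing one cell-line partition.  A single master seed
# deterministically derives substream seeds per stage and per drug, so
# enlarging a panel never perturbs already-generated drugs.

#' Simulate an expression matrix with a paired response
#'
#' Features are standard normal ("expression-like" after per-gene
#' standardization).  The continuous response is a sparse linear signal
#' over `n_informative` features (optionally plus one pairwise
#' interaction) with additive Gaussian noise.  Class labels discretize the
#' *noiseless* signal at its empirical quantiles matching
#' `class_fractions`, so the realized class counts match the requested
#' fractions to within rounding; labels are therefore predictable from the
#' features in the noise-free limit but are not a deterministic function
#' of the noisy `y`.
#'
#' @param n,p samples and features.
#' @param n_informative number of features with nonzero coefficients.
#' @param noise_sd standard deviation of the additive response noise.
#' @param class_fractions class fractions in ascending-response order; the
#'   first entry is the sensitive (low-response) class.  Length 2 gives
#'   labels `c(1, 0)` (sensitive/resistant), length 3 gives `c(1, 2, 3)`.
#' @param interaction add one product term of the first two informative
#'   features.
#' @param seed master seed; fully determines the output.
#' @returns A list with `x` (rownames `CL_...`), `y`, `d`, and `truth`
#'   (coefficients, noiseless signal, signal-scale thresholds, config).
#' @examples
#' sim <- simulate_expression_response(n = 100, p = 20, seed = 1)
#' table(sim$d)
#' @export
simulate_expression_response <- function(n, p, n_informative = min(10, p),
                                         noise_sd = 1,
                                         class_fractions = c(0.3, 0.7),
                                         interaction = FALSE,
                                         seed = NULL) {
  stopifnot(n >= 2, p >= 1, n_informative >= 1, n_informative <= p,
            noise_sd >= 0, length(class_fractions) %in% c(2, 3),
            all(class_fractions > 0),
            abs(sum(class_fractions) - 1) < 1e-8)
  if (any(round(class_fractions * n) < 1))
    stop("class fractions are infeasible for n = ", n)
  with_local_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("CL_%04d", seq_len(n)),
                                sprintf("gene_%03d", seq_len(p))))
    beta <- numeric(p)
    beta[seq_len(n_informative)] <-
      sample(c(-1, 1), n_informative, replace = TRUE) *
      runif(n_informative, 0.5, 1.5)
    signal <- drop(x %*% beta)
    if (interaction) signal <- signal + x[, 1] * x[, 2]
    y <- signal + rnorm(n, 0, noise_sd)
    k <- length(class_fractions)
    thr <- quantile(signal, cumsum(class_fractions)[-k], names = FALSE,
                    type = 1)
    band_labels <- if (k == 2) c(1, 0) else c(1, 2, 3)
    d <- band_labels[findInterval(signal, thr, left.open = TRUE) + 1L]
    list(x = x, y = setNames(y, rownames(x)), d = setNames(d, rownames(x)),
         truth = list(beta = beta, signal = signal, thresholds = thr,
                      band_labels = band_labels, noise_sd = noise_sd,
                      class_fractions = class_fractions, seed = seed))
  })
}

#' Simulate a raw dose-response panel with known CMax viabilities
#'
#' For every drug/cell-line pair a two-parameter logistic dose-response
#' curve is drawn (log-midpoint uniform over the tested log-concentration
#' range, slope uniform in `[0.5, 2]`); replicate viabilities add Gaussian
#' noise.  Each drug receives one CMax concentration, drawn log-uniformly
#' inside the tested range, except for a fraction `frac_cmax_outside`
#' placed below the lowest tested dose (downstream code must flag these as
#' extrapolated).  True CMax viabilities are computed analytically from
#' the generating curves.
#'
#' @param n_drugs,n_cell_lines panel dimensions.
#' @param concentrations tested concentrations (µM); default nine
#'   half-log dilutions from 0.001 to 10.
#' @param replicates technical replicates per concentration.
#' @param noise_sd viability noise standard deviation.
#' @param frac_cmax_outside fraction of drugs whose CMax lies outside the
#'   tested range.
#' @param seed master seed; per-drug substreams are derived from it.
#' @returns A list with `points` (drug, cell_line, concentration_uM,
#'   viability), `cmax_table` (drug, cmax_uM), `true_viability` (cell
#'   lines x drugs), and `truth` (curve parameters).
#' @export
simulate_dose_response_panel <- function(n_drugs = 5, n_cell_lines = 20,
                                         concentrations =
                                           10^seq(-3, 1, length.out = 9),
                                         replicates = 2, noise_sd = 0.03,
                                         frac_cmax_outside = 0.1,
                                         seed = NULL) {
  stopifnot(n_drugs >= 1, n_cell_lines >= 1, replicates >= 1,
            all(concentrations > 0), noise_sd >= 0,
            frac_cmax_outside >= 0, frac_cmax_outside <= 1)
  drug_seeds <- derive_seeds(seed, n_drugs + 1L)
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  cells <- sprintf("CL_%04d", seq_len(n_cell_lines))
  lc <- log(range(concentrations))
  conc <- rep(concentrations, each = replicates)

  n_out <- round(frac_cmax_outside * n_drugs)
  cmax <- with_local_seed(drug_seeds[n_drugs + 1L], {
    cm <- exp(runif(n_drugs, lc[1], lc[2]))
    if (n_out > 0) {
      out_idx <- sample.int(n_drugs, n_out)
      cm[out_idx] <- min(concentrations) * runif(n_out, 0.05, 0.5)
    }
    cm
  })

  pts <- vector("list", n_drugs)
  true_v <- matrix(NA_real_, n_cell_lines, n_drugs,
                   dimnames = list(cells, drugs))
  pars <- vector("list", n_drugs)
  for (j in seq_len(n_drugs)) {
    one <- with_local_seed(drug_seeds[j], {
      m <- runif(n_cell_lines, lc[1], lc[2])
      s <- runif(n_cell_lines, 0.5, 2)
      points <- do.call(rbind, lapply(seq_len(n_cell_lines), function(i) {
        v <- 1 / (1 + exp(s[i] * (log(conc) - m[i]))) +
          rnorm(length(conc), 0, noise_sd)
        data.frame(drug = drugs[j], cell_line = cells[i],
                   concentration_uM = conc, viability = v)
      }))
      list(m = m, s = s, points = points)
    })
    pts[[j]] <- one$points
    pars[[j]] <- data.frame(drug = drugs[j], cell_line = cells,
                            log_mid = one$m, slope = one$s)
    true_v[, j] <- pmin(pmax(
      1 / (1 + exp(one$s * (log(cmax[j]) - one$m))), 0), 1)
  }
  list(points = do.call(rbind, pts),
       cmax_table = data.frame(drug = drugs, cmax_uM = cmax),
       true_viability = true_v,
       truth = list(curves = do.call(rbind, pars), noise_sd = noise_sd,
                    concentrations = concentrations,
                    replicates = replicates, seed = seed))
}

#' Simulate a multi-drug panel sharing one cell-line partition
#'
#' Generates one expression matrix and, per drug, a viability-scale
#' response: a drug-specific sparse linear signal is squashed through the
#' logistic function onto `[0, 1]` (low values = sensitive), measurement
#' noise is added and the result clipped to `[0, 1]`.  Labels discretize
#' the noiseless viability at its quantiles matching `class_fractions`.
#' All drugs share the same train/calibration/test cell-line partition, as
#' required for cell-line-centric prioritization.
#'
#' @inheritParams simulate_expression_response
#' @param n_drugs number of drugs.
#' @param noise_sd viability-scale measurement noise.
#' @param split_fractions train/calibration/test fractions.
#' @param seed master seed; per-drug effects come from derived substreams.
#' @returns A list with `x`, `split` (a [split_spec()]), `drugs` (named
#'   list with `y`, `d`, `truth` per drug), `viability` and `labels`
#'   matrices (cell lines x drugs, noisy viabilities and noiseless-signal
#'   labels).
#' @export
simulate_shared_panel <- function(n_drugs = 8, n = 200, p = 20,
                                  n_informative = 8, noise_sd = 0.05,
                                  class_fractions = c(0.3, 0.7),
                                  split_fractions = c(0.7, 0.15, 0.15),
                                  seed = NULL) {
  seeds <- derive_seeds(seed, n_drugs + 2L)
  base <- with_local_seed(seeds[n_drugs + 1L], {
    matrix(rnorm(n * p), n, p,
           dimnames = list(sprintf("CL_%04d", seq_len(n)),
                           sprintf("gene_%03d", seq_len(p))))
  })
  split <- split_spec(rownames(base), split_fractions,
                      seed = seeds[n_drugs + 2L])
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  k <- length(class_fractions)
  band_labels <- if (k == 2) c(1, 0) else c(1, 2, 3)
  viab <- lab <- matrix(NA_real_, n, n_drugs,
                        dimnames = list(rownames(base), drugs))
  per_drug <- setNames(vector("list", n_drugs), drugs)
  for (j in seq_len(n_drugs)) {
    per_drug[[j]] <- with_local_seed(seeds[j], {
      beta <- numeric(p)
      idx <- sample.int(p, n_informative)
      beta[idx] <- sample(c(-1, 1), n_informative, TRUE) *
        runif(n_informative, 0.8, 2)
      signal <- plogis(drop(base %*% beta) / sqrt(n_informative))
      y <- pmin(pmax(signal + rnorm(n, 0, noise_sd), 0), 1)
      thr <- quantile(signal, cumsum(class_fractions)[-k],
                      names = FALSE, type = 1)
      d <- band_labels[findInterval(signal, thr, left.open = TRUE) + 1L]
      list(y = setNames(y, rownames(base)),
           d = setNames(d, rownames(base)),
           truth = list(beta = beta, signal = signal, thresholds = thr))
    })
    viab[, j] <- per_drug[[j]]$y
    lab[, j] <- per_drug[[j]]$d
  }
  list(x = base, split = split, drugs = per_drug, viability = viab,
       labels = lab, band_labels = band_labels,
       config = list(n_drugs = n_drugs, n = n, p = p,
                     n_informative = n_informative, noise_sd = noise_sd,
                     class_fractions = class_fractions,
                     split_fractions = split_fractions, seed = seed))
}
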