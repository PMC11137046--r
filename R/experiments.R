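# Repeated-split coverage experiments: the empirical check of the
# marginal (and class-conditional) coverage guarantee on exchangeable
# synthetic data.

#' Empirical coverage of the conformal pipeline over repeated splits
#'
#' Generates `n_reps` independent synthetic data sets (fresh feature
#' matrix, responses and train/calibration/test split per repetition),
#' runs [run_cp_pipeline()] on each, and collects the test-set coverage
#' diagnostics per score.  Under exchangeability the expected marginal
#' coverage lies in `[1 - alpha, 1 - alpha + 1/(n_cal + 1)]`; this
#' function measures how close the empirical mean gets.
#'
#' @param n_reps number of independent repetitions (seeds).
#' @param n,p,n_informative,noise_sd,class_fractions forwarded to
#'   [simulate_expression_response()].
#' @param alpha maximal allowed error rate.
#' @param scores score functions to evaluate.
#' @param num_trees,min_node_size forest size parameters.
#' @param split_fractions train/calibration/test fractions.
#' @param seed master seed; one substream per repetition.
#' @returns A data frame with one row per (repetition, score):
#'   `coverage`, `efficiency` (classification), `rel_width` (regression),
#'   and one `coverage_<class>` column per class.
#' @examples
#' \donttest{
#' ex <- cp_coverage_experiment(n_reps = 3, n = 300, p = 10,
#'                              num_trees = 30, seed = 1)
#' aggregate(coverage ~ score, ex, mean)
#' }
#' @export
cp_coverage_experiment <- function(n_reps = 50, n = 2000, p = 20,
                                   n_informative = 10, noise_sd = 1,
                                   class_fractions = c(0.3, 0.7),
                                   alpha = 0.1,
                                   scores = c("tc", "quantile"),
                                   num_trees = 100, min_node_size = 5,
                                   split_fractions = c(0.7, 0.15, 0.15),
                                   seed = 1) {
  rep_seeds <- derive_seeds(seed, n_reps)
  labels <- if (length(class_fractions) == 2) c(1, 0) else c(1, 2, 3)
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- rep_seeds[r]
    sim <- simulate_expression_response(
      n = n, p = p, n_informative = n_informative, noise_sd = noise_sd,
      class_fractions = class_fractions, seed = s)
    sp <- split_spec(rownames(sim$x), split_fractions, seed = s)
    res <- run_cp_pipeline(sim$x, sim$y, sim$d, sp, alpha = alpha,
                           scores = scores, num_trees = num_trees,
                           min_node_size = min_node_size, seed = s)
    do.call(rbind, lapply(names(res$reports), function(sc) {
      rp <- res$reports[[sc]]
      row <- data.frame(rep = r, score = sc,
                        coverage = rp$marginal_coverage,
                        efficiency = if (is.null(rp$efficiency)) NA_real_
                        else rp$efficiency,
                        rel_width =
                          if (is.null(rp$mean_relative_width)) NA_real_
                        else rp$mean_relative_width)
      for (cl in labels) {
        cc <- rp$per_class_coverage[as.character(cl)]
        row[[paste0("coverage_", cl)]] <-
          if (is.null(rp$per_class_coverage)) NA_real_
        else unname(cc)
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_cal") <- round(split_fractions[2] * n)
  attr(out, "alpha") <- alpha
  out
}
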