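# Cell-line-centric drug prioritization: filter drugs whose conformal
# class set is exactly {sensitive}, rank them by the upper limit of the
# conformal regression interval (ascending = most effective first).

#' Assemble per-drug conformal predictions into a shared panel
#'
#' Builds the long-format table the prioritization functions operate on.
#' Every drug must provide predictions for the identical set of test cell
#' lines: a cell line can only be prioritized if it was unseen by all
#' drug-specific models.
#'
#' @param predictions named list (one element per drug) of lists with
#'   elements `cell_line`, `set` (list of label vectors), `lower`,
#'   `upper`, and optionally `point_class`, `point_value`.
#' @returns A data frame of class `drug_panel_prediction` with one row per
#'   (cell line, drug) and a `set` list-column.
#' @export
drug_panel_prediction <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 1,
            !is.null(names(predictions)))
  rows <- lapply(names(predictions), function(dr) {
    p <- predictions[[dr]]
    n <- length(p$cell_line)
    stopifnot(length(p$set) == n, length(p$lower) == n,
              length(p$upper) == n)
    df <- data.frame(cell_line = as.character(p$cell_line), drug = dr,
                     lower = as.numeric(p$lower),
                     upper = as.numeric(p$upper),
                     point_class = if (is.null(p$point_class)) NA
                     else p$point_class,
                     point_value = if (is.null(p$point_value)) NA_real_
                     else as.numeric(p$point_value))
    df$set <- unname(p$set)
    df
  })
  panel <- do.call(rbind, rows)
  cells <- sort(unique(panel$cell_line))
  for (dr in names(predictions)) {
    have <- sort(panel$cell_line[panel$drug == dr])
    if (!identical(have, cells))
      stop("all drugs must share the same test cell lines; drug ", dr,
           " differs")
  }
  class(panel) <- c("drug_panel_prediction", class(panel))
  panel
}

panel_rows <- function(panel, cell_line) {
  rows <- panel[panel$cell_line == as.character(cell_line), , drop = FALSE]
  if (nrow(rows) == 0) stop("cell line ", cell_line, " not in panel")
  missing <- setdiff(unique(panel$drug), rows$drug)
  if (length(missing))
    stop("missing predictions for drug(s): ",
         paste(missing, collapse = ", "))
  rows
}

#' Drugs predicted effective for one cell line
#'
#' A drug counts as effective when its conformal class set is exactly the
#' singleton sensitive class: the model is then certain (at level
#' `1 - alpha`) that the cell line responds.  Full sets, empty sets, and
#' sets containing any other class are excluded.
#'
#' @param panel a [drug_panel_prediction()].
#' @param cell_line cell-line id.
#' @param sensitive class code denoting sensitivity (default 1).
#' @returns Character vector of effective drug ids.
#' @export
effective_drugs <- function(panel, cell_line, sensitive = 1) {
  rows <- panel_rows(panel, cell_line)
  eff <- vapply(rows$set, function(s)
    length(s) == 1 && as.character(s) == as.character(sensitive),
    logical(1))
  rows$drug[eff]
}

#' Rank effective drugs by the upper conformal interval limit
#'
#' Sorts the effective drugs ascendingly by the upper limit of their
#' conformal regression interval: the upper limit is a viability value
#' that will not be exceeded with high probability, so a small upper limit
#' certifies strong predicted efficacy.  Ties are broken by the point
#' prediction, then by drug id.
#'
#' @inheritParams effective_drugs
#' @param effective optional precomputed effective drug set; defaults to
#'   [effective_drugs()].
#' @returns A data frame (class `prioritized_list`) with columns `rank`,
#'   `drug`, `upper`, `point_value` and attribute `cell_line`; zero rows
#'   when no drug is effective.
#' @export
rank_drugs <- function(panel, cell_line, effective = NULL, sensitive = 1) {
  rows <- panel_rows(panel, cell_line)
  if (is.null(effective))
    effective <- effective_drugs(panel, cell_line, sensitive)
  rows <- rows[rows$drug %in% effective, , drop = FALSE]
  ord <- order(rows$upper, rows$point_value, rows$drug)
  out <- data.frame(rank = seq_len(nrow(rows)), drug = rows$drug[ord],
                    upper = rows$upper[ord],
                    point_value = rows$point_value[ord])
  attr(out, "cell_line") <- as.character(cell_line)
  class(out) <- c("prioritized_list", class(out))
  out
}

#' Evaluate a prioritized drug list against the ground truth
#'
#' Computes the evaluation measures of the cell-line-centric analysis:
#' the precision of the effective list (fraction of listed drugs that are
#' truly sensitive), whether the actually most efficient drug (lowest true
#' viability) is contained, the rank of the predicted first drug in the
#' true ascending-viability ordering of all panel drugs, whether that
#' first drug is a true positive, and the viability gap between it and the
#' true best drug.
#'
#' @param ranked a [rank_drugs()] list.
#' @param true_viability named vector of true CMax viabilities for all
#'   panel drugs of this cell line.
#' @param true_labels named vector of true class labels for the same
#'   drugs.
#' @param sensitive class code denoting sensitivity.
#' @returns A list with `defined`, `n_listed`, `precision`,
#'   `best_contained`, `first_rank`, `first_is_tp`, `viability_gap`; when
#'   the list is empty all measures are `NA` with `defined = FALSE`.
#' @export
evaluate_prioritization <- function(ranked, true_viability, true_labels,
                                    sensitive = 1) {
  stopifnot(!is.null(names(true_viability)),
            all(names(true_labels) == names(true_viability)))
  if (nrow(ranked) == 0)
    return(list(defined = FALSE, n_listed = 0L, precision = NA_real_,
                best_contained = NA, first_rank = NA_real_,
                first_is_tp = NA, viability_gap = NA_real_))
  if (!all(ranked$drug %in% names(true_viability)))
    stop("truth is missing for some listed drugs")
  listed <- ranked$drug
  prec <- mean(true_labels[listed] == sensitive)
  best <- names(true_viability)[which.min(true_viability)]
  first <- listed[1]
  rk <- rank(true_viability, ties.method = "min")
  list(defined = TRUE, n_listed = length(listed), precision = prec,
       best_contained = best %in% listed,
       first_rank = as.numeric(rk[[first]]),
       first_is_tp = unname(true_labels[first] == sensitive),
       viability_gap = abs(true_viability[[first]] -
                           min(true_viability)))
}

#' Prioritize and evaluate every test cell line of a panel
#'
#' Runs [effective_drugs()], [rank_drugs()] and
#' [evaluate_prioritization()] for each cell line of the panel and
#' aggregates: medians for precision and first-drug rank (over cell lines
#' with a non-empty effective list) and fractions for the flags.
#'
#' @inheritParams effective_drugs
#' @param true_viability cell lines x drugs matrix of true viabilities.
#' @param true_labels cell lines x drugs matrix of true labels.
#' @returns A list with `per_cell_line` (data frame) and `aggregate`
#'   (medians / fractions, plus the fraction of cell lines with an empty
#'   list).
#' @export
prioritize_panel <- function(panel, true_viability, true_labels,
                             sensitive = 1) {
  cells <- sort(unique(panel$cell_line))
  drugs <- unique(panel$drug)
  stopifnot(all(cells %in% rownames(true_viability)),
            all(drugs %in% colnames(true_viability)))
  per <- lapply(cells, function(cl) {
    ranked <- rank_drugs(panel, cl, sensitive = sensitive)
    ev <- evaluate_prioritization(
      ranked, setNames(true_viability[cl, drugs], drugs),
      setNames(true_labels[cl, drugs], drugs), sensitive)
    data.frame(cell_line = cl, n_listed = ev$n_listed,
               precision = ev$precision,
               best_contained = ev$best_contained,
               first_rank = ev$first_rank, first_is_tp = ev$first_is_tp,
               viability_gap = ev$viability_gap)
  })
  per <- do.call(rbind, per)
  def <- !is.na(per$precision)
  aggregate <- list(
    n_cell_lines = nrow(per),
    frac_empty = mean(!def),
    median_precision = median(per$precision[def]),
    median_first_rank = median(per$first_rank[def]),
    frac_best_contained = mean(per$best_contained[def]),
    frac_first_tp = mean(per$first_is_tp[def]),
    frac_gap_below_0.1 = mean(per$viability_gap[def] < 0.1))
  list(per_cell_line = per, aggregate = aggregate)
}
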