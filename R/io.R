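# Delimited-text readers and writers for the pipeline's tabular formats.
# All tables are tab-separated with a header row; feature matrices carry
# the sample id in the first column and feature ids in the header.

read_table_checked <- function(path, required, what) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a feature matrix from delimited text
#'
#' Expects a tab-separated file with the sample id in the first column and
#' feature ids in the header row (samples in rows).
#'
#' @param path input file.
#' @returns Numeric matrix with sample ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) stop("missing values in feature matrix ", path)
  m
}

#' Write a feature matrix as delimited text
#'
#' @param x numeric matrix, samples in rows.
#' @param path output file.
#' @returns `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a response table
#'
#' Responses are stored as a tab-separated table with columns `sample_id`,
#' `y` (continuous response) and `d` (discrete response).
#'
#' @param path file path.
#' @returns `read_response_table`: a data frame with those columns.
#' @export
read_response_table <- function(path) {
  read_table_checked(path, c("sample_id", "y", "d"), "response")
}

#' @rdname read_response_table
#' @param y,d named (by sample id) continuous and discrete responses.
#' @export
write_response_table <- function(y, d, path) {
  write.table(data.frame(sample_id = names(y), y = unname(y),
                         d = unname(d)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read raw dose-response points
#'
#' @param path tab-separated file with columns `drug`, `cell_line`,
#'   `concentration_uM`, `viability`.
#' @returns Data frame of dose-response points.
#' @export
read_dose_response <- function(path) {
  df <- read_table_checked(path, c("drug", "cell_line",
                                   "concentration_uM", "viability"),
                           "dose-response")
  if (any(df$concentration_uM <= 0))
    stop("concentrations must be strictly positive")
  df
}

#' Read a CMax concentration table
#'
#' @param path tab-separated file with columns `drug`, `cmax_uM` (peak
#'   plasma concentration at the highest recommended dose).
#' @returns Data frame with one row per drug.
#' @export
read_cmax_table <- function(path) {
  df <- read_table_checked(path, c("drug", "cmax_uM"), "CMax")
  if (any(df$cmax_uM <= 0)) stop("CMax concentrations must be positive")
  df
}

#' Write a coverage/diagnostics report as delimited text
#'
#' One row per model/drug with coverage, per-class coverage, efficiency
#' and mean relative interval width (columns absent measures are NA).
#'
#' @param reports named list of [cp_evaluate()] reports.
#' @param path output file.
#' @returns `path`, invisibly.
#' @export
write_coverage_reports <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    pc <- if (!is.null(r$per_class_coverage))
      paste(names(r$per_class_coverage),
            signif(r$per_class_coverage, 6), sep = "=", collapse = ";")
    else NA_character_
    data.frame(model = nm, task = r$task, n = r$n,
               marginal_coverage = r$marginal_coverage,
               per_class_coverage = pc,
               efficiency = if (is.null(r$efficiency)) NA_real_
               else r$efficiency,
               mean_relative_width =
                 if (is.null(r$mean_relative_width)) NA_real_
               else r$mean_relative_width)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write prediction sets and intervals as delimited text
#'
#' @param sets list of label vectors (may be `NULL`).
#' @param intervals data frame of intervals (may be `NULL`).
#' @param ids sample ids.
#' @param path output file.
#' @returns `path`, invisibly.
#' @export
write_cp_predictions <- function(sets, intervals, ids, path) {
  df <- data.frame(sample_id = ids)
  if (!is.null(sets))
    df$set <- vapply(sets, function(s) paste(s, collapse = "|"),
                     character(1))
  if (!is.null(intervals)) {
    df$lower <- intervals$lower
    df$upper <- intervals$upper
    df$degenerate <- intervals$degenerate
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
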