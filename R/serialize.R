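# On-disk model format: a plain-text container with a key/value header
# followed by one block per tree.  Doubles are written with "%.17g" so a
# reloaded forest reproduces predictions bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)
fmt_int <- function(x) sprintf("%d", as.integer(x))

#' Serialize a SAURON-RF forest to a text file
#'
#' Writes the complete fitted forest (parameters, training responses,
#' sample weights, and all tree node/leaf arrays) to a structured text
#' file.  [read_sauron()] restores an object whose predictions, quantiles
#' and sample weights are bit-identical to the original fit.
#'
#' @param object a [sauron_rf()] fit.
#' @param path output file path.
#' @returns `path`, invisibly.
#' @export
write_sauron <- function(object, path) {
  stopifnot(inherits(object, "sauron_rf"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("sauronCP-forest v1")
  wl("num_trees\t", fmt_int(object$num_trees))
  wl("mtry\t", fmt_int(object$mtry))
  wl("min_node_size\t", fmt_int(object$min_node_size))
  wl("n\t", fmt_int(object$n))
  wl("p\t", fmt_int(object$p))
  wl("scheme\t", object$scheme)
  wl("g\t", if (is.null(object$g)) "NA" else fmt_num(object$g))
  wl("seed\t", if (is.null(object$seed)) "NA" else fmt_int(object$seed))
  wl("classes\t", paste(object$classes, collapse = " "))
  wl("modal_class\t", as.character(object$modal_class))
  wl("thresholds\t", if (is.null(object$thresholds)) "NA"
     else paste(fmt_num(object$thresholds), collapse = " "))
  wl("feature_names\t", paste(object$feature_names, collapse = " "))
  wl("sample_ids\t", if (is.null(object$sample_ids)) "NA"
     else paste(object$sample_ids, collapse = " "))
  wl("y\t", paste(fmt_num(object$y), collapse = " "))
  wl("d\t", paste(object$d, collapse = " "))
  wl("w_star\t", paste(fmt_num(object$w_star), collapse = " "))
  wl("tree_seeds\t", paste(fmt_int(object$tree_seeds), collapse = " "))
  int_fields <- c("split_var", "left", "right", "node_leaf", "leaf_ptr",
                  "leaf_members", "leaf_mode", "boot_ids")
  num_fields <- c("split_val", "leaf_w", "leaf_pred")
  for (b in seq_len(object$num_trees)) {
    tr <- object$trees[[b]]
    wl("tree\t", fmt_int(b))
    for (f in int_fields) wl(f, "\t", paste(fmt_int(tr[[f]]),
                                            collapse = " "))
    for (f in num_fields) wl(f, "\t", paste(fmt_num(tr[[f]]),
                                            collapse = " "))
  }
  invisible(path)
}

#' Restore a serialized SAURON-RF forest
#'
#' @param path file written by [write_sauron()].
#' @returns A `sauron_rf` object.
#' @export
read_sauron <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "sauronCP-forest v1")
    stop("not a sauronCP forest file: ", path)
  kv <- strsplit(lines[-1], "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(z) if (length(z) > 1) z[[2]] else "",
                 character(1))
  top <- function(key) vals[which(keys == key)[1]]
  nums <- function(s) if (identical(s, "NA")) NULL
  else as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  ints <- function(s) as.integer(strsplit(s, " ", fixed = TRUE)[[1]])
  chars <- function(s) if (identical(s, "NA")) NULL
  else strsplit(s, " ", fixed = TRUE)[[1]]

  classes_chr <- chars(top("classes"))
  classes <- suppressWarnings(as.numeric(classes_chr))
  if (anyNA(classes)) classes <- classes_chr
  d_chr <- chars(top("d"))
  d <- if (is.numeric(classes)) as.numeric(d_chr) else d_chr

  tree_rows <- which(keys == "tree")
  int_fields <- c("split_var", "left", "right", "node_leaf", "leaf_ptr",
                  "leaf_members", "leaf_mode", "boot_ids")
  num_fields <- c("split_val", "leaf_w", "leaf_pred")
  trees <- lapply(tree_rows, function(r) {
    blk <- setNames(vals[r + seq_len(11)], keys[r + seq_len(11)])
    tr <- c(lapply(blk[int_fields], ints), lapply(blk[num_fields], nums))
    tr[c("split_var", "split_val", "left", "right", "node_leaf",
         "leaf_ptr", "leaf_members", "leaf_w", "leaf_pred", "leaf_mode",
         "boot_ids")]
  })

  y <- nums(top("y"))
  counts <- as.integer(table(factor(d, levels = classes)))
  names(counts) <- as.character(classes)
  modal <- if (is.numeric(classes)) as.numeric(top("modal_class"))
  else top("modal_class")
  g <- nums(top("g"))
  structure(list(trees = trees, classes = classes, modal_class = modal,
                 counts = counts, y = y, d = d,
                 thresholds = nums(top("thresholds")),
                 w_star = nums(top("w_star")), scheme = top("scheme"),
                 g = if (length(g)) g else NULL,
                 num_trees = as.integer(top("num_trees")),
                 mtry = as.integer(top("mtry")),
                 min_node_size = as.integer(top("min_node_size")),
                 seed = if (identical(top("seed"), "NA")) NULL
                 else as.integer(top("seed")),
                 tree_seeds = ints(top("tree_seeds")),
                 feature_names = chars(top("feature_names")),
                 sample_ids = chars(top("sample_ids")),
                 n = as.integer(top("n")), p = as.integer(top("p"))),
            class = "sauron_rf")
}
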