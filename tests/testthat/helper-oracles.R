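# Independent oracles used across the suite.  They recompute quantities
# from first principles (R loops over the raw tree arrays / brute-force
# enumeration) and never call the code paths they check.

# route one query through a stored tree, in R
oracle_drop <- function(tree, xq) {
  v <- 1L
  while (tree$split_var[v] != -1L) {
    v <- if (xq[tree$split_var[v] + 1L] <= tree$split_val[v])
      tree$left[v] + 1L else tree$right[v] + 1L
  }
  v
}

# Standard quantile-regression-forest weights (Meinshausen): per tree the
# query's co-leaf bootstrap members get weight (copies in leaf)/(leaf
# size); trees average with 1/B.  Leaf membership is recomputed here by
# routing every bootstrap sample through the tree.
oracle_qrf_weights <- function(fit, xq) {
  n <- fit$n
  w <- numeric(n)
  xtr <- attr(fit, "oracle_xtrain")
  for (tr in fit$trees) {
    leaf_of_boot <- vapply(tr$boot_ids + 1L, function(i)
      oracle_drop(tr, xtr[i, ]), integer(1))
    q_leaf <- oracle_drop(tr, xq)
    in_leaf <- which(leaf_of_boot == q_leaf)
    ids <- tr$boot_ids[in_leaf] + 1L
    for (i in ids) w[i] <- w[i] + (1 / fit$num_trees) / length(in_leaf)
  }
  w
}

oracle_qrf_quantile <- function(fit, xq, levels) {
  w <- oracle_qrf_weights(fit, xq)
  ord <- order(fit$y)
  cdf <- cumsum(w[ord])
  vapply(levels, function(lv)
    fit$y[ord][which(cdf >= lv - 1e-9)[1]], numeric(1))
}

# Brute-force 1-D k-medoids: enumerate every medoid subset, minimize the
# summed absolute distance to the nearest medoid.  (Optimal medoid sets
# can tie, e.g. for even cluster sizes, so the cost is also returned.)
kmedoids_cost <- function(values, medoids) {
  sum(apply(abs(outer(values, medoids, "-")), 1, min))
}

oracle_kmedoids <- function(values, k) {
  idx <- utils::combn(seq_along(values), k)
  cost <- apply(idx, 2, function(j) kmedoids_cost(values, values[j]))
  list(medoids = sort(values[idx[, which.min(cost)]]), cost = min(cost))
}

# Hand-build a forest of single-leaf "trees" with prescribed leaf
# members, weights, predictions and class modes, for exact checks of the
# vote/tree-weight arithmetic.  `leaves` is a list with one element per
# tree: list(members = 0-based ids, w = normalized weights, pred, mode).
toy_forest <- function(leaves, y, classes, modal_class, p = 1) {
  trees <- lapply(leaves, function(lf) {
    list(split_var = -1L, split_val = 0, left = -1L, right = -1L,
         node_leaf = 0L, leaf_ptr = c(0L, length(lf$members)),
         leaf_members = as.integer(lf$members), leaf_w = as.numeric(lf$w),
         leaf_pred = as.numeric(lf$pred), leaf_mode = as.integer(lf$mode),
         boot_ids = as.integer(lf$members))
  })
  d <- rep(classes[1], length(y))
  structure(list(trees = trees, classes = classes,
                 modal_class = modal_class,
                 counts = setNames(rep(1L, length(classes)),
                                   as.character(classes)),
                 y = y, d = d, thresholds = NULL,
                 w_star = rep(1, length(y)), scheme = "custom", g = NULL,
                 num_trees = length(trees), mtry = 1, min_node_size = 1,
                 seed = NULL, tree_seeds = seq_along(trees),
                 feature_names = paste0("f", seq_len(p)),
                 sample_ids = NULL, n = length(y), p = p),
            class = "sauron_rf")
}

# small fitted forest with the training matrix attached for the oracles
fit_with_xtrain <- function(x, y, d, ...) {
  fit <- sauron_rf(x, y, d, ...)
  attr(fit, "oracle_xtrain") <- x
  fit
}
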