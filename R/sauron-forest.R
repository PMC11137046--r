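# Simultaneous regression+classification random forest with a
# quantile-regression extension.  Tree growth lives in src/sauron.cpp.

# run `expr` under set.seed(seed) without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# derive n deterministic 32-bit substream seeds from one master seed
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(2147483646L, n, replace = TRUE))
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x))) stop("'x' contains non-finite values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("sample ids (rownames of 'x') must be unique")
  x
}

#' Fit a simultaneous regression and classification random forest
#'
#' Grows `num_trees` regression trees on bootstrap samples of size N,
#' propagating class-imbalance sample weights (see
#' [compute_sample_weights()]) through the split criterion: splits maximize
#' the improvement in *weighted* MSE among `mtry` randomly drawn candidate
#' features.  Each leaf stores its members' normalized weights (used for
#' the leaf average), and the mode of their class labels, which turns every
#' tree into a classifier.  A node becomes a leaf when it has fewer than
#' `2 * min_node_size` bootstrap members, its responses are constant, or no
#' admissible split exists; every leaf keeps at least `min_node_size`
#' members.
#'
#' @param x numeric feature matrix, samples in rows (sample ids as
#'   rownames, feature ids as colnames).
#' @param y numeric continuous response, length `nrow(x)`.
#' @param d discrete class labels, length `nrow(x)`; see
#'   [response_bundle()] for coding conventions.
#' @param thresholds optional discretization thresholds relating `d` to
#'   `y`; required by the distance-based weight schemes.
#' @param weights weight scheme (`"simple"`, `"linear"`, `"quadratic"`) or
#'   a precomputed numeric vector of per-sample weights.
#' @param g distance exponent for the linear/quadratic schemes.
#' @param num_trees number of trees B.
#' @param mtry features sampled per split; default `ceiling(P / 3)`.
#' @param min_node_size minimum bootstrap members per leaf.
#' @param seed integer; fixes all bootstrap and feature-sampling streams
#'   (one master seed deterministically derives one substream per tree).
#' @returns An object of class `sauron_rf`; see [predict.sauron_rf()].
#' @examples
#' sim <- simulate_expression_response(n = 80, p = 10, seed = 1)
#' fit <- sauron_rf(sim$x, sim$y, sim$d, num_trees = 25, seed = 1)
#' fit
#' @seealso [predict.sauron_rf()], [forest_sample_weights()],
#'   [tree_predict()], [write_sauron()]
#' @export
sauron_rf <- function(x, y, d, thresholds = NULL,
                      weights = c("simple", "linear", "quadratic"), g = NULL,
                      num_trees = 100, mtry = NULL, min_node_size = 5,
                      seed = NULL) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  bundle <- response_bundle(y, d, thresholds)
  stopifnot(num_trees >= 1, min_node_size >= 1)
  if (n < min_node_size)
    stop("fewer samples (", n, ") than 'min_node_size' (", min_node_size,
         ")")
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  if (mtry < 1 || mtry > p) stop("'mtry' must be in [1, ", p, "]")

  if (is.numeric(weights)) {
    stopifnot(length(weights) == n, all(is.finite(weights)),
              all(weights >= 0))
    w_star <- weights
    scheme <- "custom"
  } else {
    scheme <- match.arg(weights)
    if (length(bundle$classes) < 2) {
      warning("only one class present; falling back to uniform weights")
      w_star <- rep(1, n)
    } else {
      w_star <- as.numeric(compute_sample_weights(bundle, scheme, g))
    }
  }

  tree_seeds <- derive_seeds(seed, num_trees)
  didx <- match(bundle$d, bundle$classes)
  trees <- .sauron_grow(x, bundle$y, w_star, didx,
                        length(bundle$classes), as.integer(num_trees),
                        as.integer(mtry), as.integer(min_node_size),
                        as.numeric(tree_seeds))
  structure(list(trees = trees, classes = bundle$classes,
                 modal_class = bundle$modal_class,
                 counts = bundle$counts, y = unname(bundle$y),
                 d = unname(bundle$d),
                 thresholds = bundle$thresholds, w_star = w_star,
                 scheme = scheme, g = g, num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, seed = seed,
                 tree_seeds = tree_seeds, feature_names = colnames(x),
                 sample_ids = rownames(x), n = n, p = p),
            class = "sauron_rf")
}

#' @export
print.sauron_rf <- function(x, ...) {
  cat("SAURON-RF forest:", x$num_trees, "trees,", x$n, "samples,",
      x$p, "features\n")
  cat("  classes:", paste(x$classes, collapse = ", "),
      "(modal:", paste0(x$modal_class, ")"),
      " weights:", x$scheme, "\n")
  cat("  mtry:", x$mtry, " min_node_size:", x$min_node_size, "\n")
  invisible(x)
}

check_newdata <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  if (ncol(newdata) != object$p)
    stop("'newdata' has ", ncol(newdata), " features; the forest expects ",
         object$p)
  storage.mode(newdata) <- "double"
  newdata
}

#' Predict from a SAURON-RF forest
#'
#' For each query the forest first classifies: every tree votes with the
#' class mode of the reached leaf and the plurality class wins (ties go to
#' the lowest class code).  The vote proportions are the forest's class
#' probabilities.  Tree weights for the regression average depend on that
#' vote: when the predicted class is the training modal class every tree
#' gets weight 1/B; otherwise only trees agreeing with the forest vote
#' contribute, with equal weight.  The point value is the tree-weighted
#' average of leaf means, identical (up to rounding) to the weighted sum of
#' training responses under the forest-wide sample weights.
#'
#' @param object a [sauron_rf()] fit.
#' @param newdata feature matrix of query samples.
#' @param type `"response"` for class votes and point predictions,
#'   `"quantile"` for conditional quantiles, `"weights"` for the raw
#'   forest-wide per-training-sample weights \eqn{w_i(x)}, or `"cdf"` for
#'   the estimated conditional distribution function on the training
#'   response support.
#' @param levels quantile levels in (0, 1] for `type = "quantile"`.
#' @param ... unused.
#' @returns For `"response"`, a list with `class`, `value`, and the vote
#'   matrix `votes`; for `"quantile"`, a matrix of quantiles (queries x
#'   levels); for `"weights"`, a queries x N weight matrix with rows
#'   summing to 1; for `"cdf"`, a list with the sorted response `support`
#'   and a step-function matrix `cdf`.
#' @examples
#' sim <- simulate_expression_response(n = 80, p = 10, seed = 1)
#' fit <- sauron_rf(sim$x, sim$y, sim$d, num_trees = 25, seed = 1)
#' pr <- predict(fit, sim$x[1:3, ])
#' pr$class
#' predict(fit, sim$x[1:3, ], type = "quantile", levels = c(0.05, 0.95))
#' @export
predict.sauron_rf <- function(object, newdata,
                              type = c("response", "quantile", "weights",
                                       "cdf"),
                              levels = c(0.05, 0.95), ...) {
  type <- match.arg(type)
  newdata <- check_newdata(object, newdata)
  want_w <- type %in% c("quantile", "weights", "cdf")
  out <- .sauron_forecast(object$trees, newdata,
                          length(object$classes),
                          match(object$modal_class, object$classes),
                          object$n, want_w)
  if (type == "response") {
    votes <- out$votes
    colnames(votes) <- as.character(object$classes)
    rownames(votes) <- rownames(newdata)
    return(list(class = object$classes[out$point_class],
                value = as.numeric(out$point_value), votes = votes))
  }
  W <- out$weights
  rownames(W) <- rownames(newdata)
  if (type == "weights") return(W)
  ord <- order(object$y)
  cdf <- t(apply(W[, ord, drop = FALSE], 1, cumsum))
  if (type == "cdf")
    return(list(support = object$y[ord], cdf = cdf))
  quantile_from_cdf(object$y[ord], cdf, levels)
}

# invert a step CDF: smallest support value whose cdf reaches the level
quantile_from_cdf <- function(support, cdf, levels) {
  stopifnot(all(levels > 0), all(levels <= 1))
  q <- matrix(NA_real_, nrow(cdf), length(levels),
              dimnames = list(rownames(cdf), paste0("q", levels)))
  for (j in seq_along(levels)) {
    hit <- cdf >= levels[j] - 1e-9
    q[, j] <- support[max.col(hit, ties.method = "first")]
  }
  q
}

#' Forest-wide training-sample weights for a query
#'
#' Returns the weight \eqn{w_i(x)} that each training sample contributes to
#' the forest prediction at `newdata`: the tree-weighted average of the
#' normalized leaf weights of the leaves the query reaches, with bootstrap
#' duplicates collapsed onto their original sample.  Rows sum to 1, and
#' `rowSums(W * y)` reproduces the forest point prediction.  These weights
#' define the estimated conditional response distribution used for
#' quantile regression.
#'
#' @inheritParams predict.sauron_rf
#' @returns A queries x N matrix of nonnegative weights with unit row sums.
#' @export
forest_sample_weights <- function(object, newdata) {
  predict(object, newdata, type = "weights")
}

#' Conditional quantile predictions
#'
#' Convenience wrapper around `predict(object, newdata, type = "quantile")`:
#' estimates the conditional CDF from the forest-wide sample weights and
#' returns, per level, the smallest training response value at which the
#' CDF reaches the level.
#'
#' @inheritParams predict.sauron_rf
#' @returns Matrix of quantiles, queries x levels.
#' @export
predict_quantile <- function(object, newdata, levels = c(0.05, 0.95)) {
  predict(object, newdata, type = "quantile", levels = levels)
}

#' Prediction of a single tree
#'
#' Evaluates one tree of the forest: the query is routed from the root to a
#' leaf and the leaf's weighted average response is returned, with leaf
#' weights equal to the class-imbalance weights of its bootstrap members
#' normalized to sum to 1.
#'
#' @inheritParams predict.sauron_rf
#' @param tree tree index in `1:num_trees`.
#' @returns Numeric vector of per-query predictions.
#' @export
tree_predict <- function(object, tree, newdata) {
  stopifnot(inherits(object, "sauron_rf"),
            tree >= 1, tree <= object$num_trees)
  newdata <- check_newdata(object, newdata)
  tr <- object$trees[[tree]]
  vapply(seq_len(nrow(newdata)), function(q) {
    v <- 1L
    while (tr$split_var[v] != -1L) {
      v <- if (newdata[q, tr$split_var[v] + 1L] <= tr$split_val[v])
        tr$left[v] + 1L else tr$right[v] + 1L
    }
    tr$leaf_pred[tr$node_leaf[v] + 1L]
  }, numeric(1))
}
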