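# Recursive-partitioning classifiers: the deviance-splitting tree and its
# bootstrap-aggregated forest. The growers live in src/tree.cpp; with one
# predictor a tree is just an ordered set of split points with per-leaf
# plurality labels.

#' Deviance of a classification-tree node
#'
#' `D_m = -2 * sum_k n_mk * log(p_mk)` with `p_mk = n_mk / n_m` and
#' `0 * log(0)` defined as 0. A pure node has deviance 0; splits are chosen to
#' minimize the summed deviance of the child nodes.
#'
#' @param counts Non-negative per-group counts (any length), not all zero.
#' @return The node deviance, a non-negative scalar.
#' @examples
#' node_deviance(c(50, 0, 0))    # pure: 0
#' node_deviance(c(50, 50, 0))   # 138.63
#' node_deviance(c(30, 30, 30))  # 197.75
#' @export
node_deviance <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  pos <- counts > 0
  -2 * sum(counts[pos] * log(counts[pos] / n))
}

#' Deviance-splitting classification tree
#'
#' Grows a binary tree on the single predictor: each split minimizes the
#' summed deviance of the two children, growth stops when no split achieves a
#' strict deviance decrease or when node-size guards bind, and each terminal
#' node predicts its plurality group (ties toward the lower group).
#'
#' @inheritParams fit_classifier
#' @param minsplit Smallest node that may be split.
#' @param minbucket Smallest admissible terminal node.
#' @return An object of class `c("mc_cart", "mc_fit")` with `breaks` (ordered
#'   interior split points), per-leaf `labels` and `counts`.
#' @examples
#' set.seed(1)
#' ds <- simulate_condition(sim_condition(topology("AB_BC"), 150, c(1, 1, 1),
#'                                        d = 1.6, pi = 0, seed = 3))
#' fit <- fit_cart(ds)
#' fit$breaks
#' @export
fit_cart <- function(data, minsplit = 20L, minbucket = 7L) {
  tr <- training_frame(data)
  ord <- order(tr$x)
  tree <- cpp_grow_tree(tr$x[ord], as.integer(tr$y[ord]) - 1L, 3L,
                        as.integer(minsplit), as.integer(minbucket))
  structure(list(method = "CART", n = length(tr$x),
                 breaks = tree$breaks, labels = tree$labels,
                 counts = tree$counts,
                 deviance = sum(apply(tree$counts, 1, node_deviance))),
            class = c("mc_cart", "mc_fit"))
}

#' @export
predict.mc_cart <- function(object, newdata, ...) {
  lab <- cpp_predict_tree(object$breaks, object$labels, newdata_x(newdata))
  as_group(GROUP_LEVELS[lab])
}

#' @export
print.mc_cart <- function(x, ...) {
  cat(sprintf(
    "Deviance classification tree: %d leaves, total leaf deviance %.2f\n",
    length(x$labels), x$deviance))
  invisible(x)
}

#' Random forest of deviance-splitting trees
#'
#' Grows `n_trees` trees, each on a bootstrap resample (with replacement, at
#' the original n) of the training cases, to purity (no node-size guards).
#' With one predictor the per-tree predictor subsample is necessarily the full
#' predictor set, so the ensemble's diversity comes from the case bootstrap
#' alone. Prediction is by majority vote across trees, ties toward the lower
#' group. Consumes the R RNG stream; `set.seed()` first for reproducibility.
#'
#' @inheritParams fit_classifier
#' @param n_trees Number of bootstrap trees (the study default is 1000; 200 is
#'   a desk-scale setting).
#' @return An object of class `c("mc_rf", "mc_fit")`.
#' @export
fit_rf <- function(data, n_trees = 1000L) {
  stopifnot(n_trees >= 1)
  tr <- training_frame(data)
  ord <- order(tr$x)
  trees <- cpp_grow_forest(tr$x[ord], as.integer(tr$y[ord]) - 1L, 3L,
                           as.integer(n_trees))
  structure(list(method = "RF", n = length(tr$x), n_trees = n_trees,
                 trees = trees),
            class = c("mc_rf", "mc_fit"))
}

#' @export
#' @rdname fit_rf
#' @param object A fitted `mc_rf`.
#' @param newdata Predictor values (numeric vector, data frame with `x`, or
#'   `mc_dataset`).
#' @param type `"label"` for majority-vote labels, `"votes"` for the per-case
#'   vote fractions.
#' @param ... Unused.
predict.mc_rf <- function(object, newdata, type = c("label", "votes"), ...) {
  type <- match.arg(type)
  votes <- cpp_forest_votes(object$trees, newdata_x(newdata), 3L)
  colnames(votes) <- GROUP_LEVELS
  if (type == "votes") {
    return(votes / object$n_trees)
  }
  score_to_label(votes)
}

#' @export
print.mc_rf <- function(x, ...) {
  cat(sprintf("Random forest: %d deviance trees on %d cases\n",
              x$n_trees, x$n))
  invisible(x)
}
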