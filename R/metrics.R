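# Misclassification-rate metrics: overall and per-group error of predicted
# labels against a reference labelling (the true, pre-noise labels by
# default).

#' Overall and per-group misclassification rates
#'
#' `group_rate_k` is the fraction of reference-group-k cases whose prediction
#' differs from the reference; `overall` is the overall mismatch fraction,
#' which equals the count-weighted mean of the group rates.
#'
#' @param pred Predicted group labels.
#' @param truth Reference group labels (every group must be present).
#' @return A list of class `mc_rates` with `overall` and `group` (named
#'   length-3 vector).
#' @examples
#' misclassification_rates(rep("A", 9), rep(c("A", "B", "C"), 3))
#' @export
misclassification_rates <- function(pred, truth) {
  pred <- as_group(pred)
  truth <- as_group(truth)
  stopifnot(length(pred) == length(truth))
  n_k <- table(truth)
  if (any(n_k == 0)) {
    stop("group(s) ", paste(names(n_k)[n_k == 0], collapse = ", "),
         " absent from the reference labels: group rate undefined")
  }
  miss <- pred != truth
  structure(list(
    overall = mean(miss),
    group = vapply(GROUP_LEVELS, function(k) mean(miss[truth == k]), 0)
  ), class = "mc_rates")
}

#' @export
print.mc_rates <- function(x, ...) {
  cat(sprintf("Misclassification: overall %.3f; groups %.3f / %.3f / %.3f\n",
              x$overall, x$group[1], x$group[2], x$group[3]))
  invisible(x)
}

#' Confusion matrix of predictions against reference labels
#'
#' @inheritParams misclassification_rates
#' @return A 3x3 contingency table (rows = reference, columns = predicted).
#' @export
confusion_matrix <- function(pred, truth) {
  table(truth = as_group(truth), predicted = as_group(pred))
}
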