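# The eight classifiers behind one fit/predict contract. Every fit_* function
# trains on the *observed* (possibly mislabeled) group labels of a dataset and
# its predict method returns a complete factor of labels in {A, B, C}.
# Prediction ties are always broken toward the lower-ordered group.

#' Classifier settings
#'
#' Tunable parameters for the eight classification methods, with the study's
#' defaults.
#'
#' @param rf_trees Number of bootstrap trees in the random forest.
#' @param cart_minsplit,cart_minbucket Minimum node size to attempt a split and
#'   minimum terminal-node size for the classification tree.
#' @param gam_lambda Fixed smoothing parameter of the thin-plate spline.
#' @param nnet_hidden,nnet_decay,nnet_maxit Hidden units, weight-decay penalty
#'   and epoch cap for the neural network.
#' @param mixda_subclasses Gaussian subclasses per group in mixture
#'   discriminant analysis.
#' @param mixda_variance `"common"` (one variance pooled over all subclasses)
#'   or `"group"` (group-specific variance shared by a group's subclasses).
#' @return A named list of class `mc_settings`.
#' @export
classifier_settings <- function(rf_trees = 1000L,
                                cart_minsplit = 20L, cart_minbucket = 7L,
                                gam_lambda = 1.4,
                                nnet_hidden = 5L, nnet_decay = 0.1,
                                nnet_maxit = 500L,
                                mixda_subclasses = 3L,
                                mixda_variance = c("common", "group")) {
  structure(list(
    rf_trees = as.integer(rf_trees),
    cart_minsplit = as.integer(cart_minsplit),
    cart_minbucket = as.integer(cart_minbucket),
    gam_lambda = gam_lambda,
    nnet_hidden = as.integer(nnet_hidden), nnet_decay = nnet_decay,
    nnet_maxit = as.integer(nnet_maxit),
    mixda_subclasses = as.integer(mixda_subclasses),
    mixda_variance = match.arg(mixda_variance)
  ), class = "mc_settings")
}

#' Method names of the eight classifiers
#' @export
CLASSIFIER_METHODS <- c("LDA", "QDA", "LR", "CART", "RF", "GAM", "MIXDA",
                        "NNET")

# Normalize training input: a mc_dataset (observed labels) or a data.frame
# with columns x and label.
training_frame <- function(data) {
  if (inherits(data, "mc_dataset")) {
    list(x = data$x, y = as_group(data$observed_label))
  } else if (is.data.frame(data)) {
    stopifnot(all(c("x", "label") %in% names(data)))
    list(x = data$x, y = as_group(data$label))
  } else {
    stop("data must be a mc_dataset or a data.frame with columns x, label")
  }
}

newdata_x <- function(newdata) {
  if (inherits(newdata, "mc_dataset")) newdata$x
  else if (is.data.frame(newdata)) newdata$x
  else as.numeric(newdata)
}

#' Fit any of the eight classifiers by name
#'
#' Uniform entry point: all methods accept the same labelled dataset (fitting
#' on its observed labels) and return an object whose `predict` method yields
#' a complete vector of group labels. Methods with internal randomness (RF,
#' NNET, MIXDA) consume the R RNG stream, so call `set.seed()` first for
#' reproducibility.
#'
#' @param method One of `r paste(CLASSIFIER_METHODS, collapse = ", ")`.
#' @param data A `mc_dataset` or a data.frame with columns `x`, `label`.
#' @param settings A [classifier_settings()] list.
#' @return A fitted classifier of class `c("mc_<method>", "mc_fit")`.
#' @examples
#' set.seed(1)
#' ds <- simulate_condition(sim_condition(topology("AB_BC"), 150, c(1, 1, 1),
#'                                        d = 1.6, pi = 0.1, seed = 7))
#' fit <- fit_classifier("LDA", ds)
#' table(predict(fit, ds), ds$true_label)
#' @export
fit_classifier <- function(method, data, settings = classifier_settings()) {
  method <- match.arg(toupper(method), CLASSIFIER_METHODS)
  switch(method,
    LDA = fit_lda(data),
    QDA = fit_qda(data),
    LR = fit_lr(data),
    CART = fit_cart(data, minsplit = settings$cart_minsplit,
                    minbucket = settings$cart_minbucket),
    RF = fit_rf(data, n_trees = settings$rf_trees),
    GAM = fit_gam(data, lambda = settings$gam_lambda),
    MIXDA = fit_mixda(data, subclasses = settings$mixda_subclasses,
                      variance = settings$mixda_variance),
    NNET = fit_nnet(data, hidden = settings$nnet_hidden,
                    decay = settings$nnet_decay,
                    maxit = settings$nnet_maxit)
  )
}

#' @export
print.mc_fit <- function(x, ...) {
  cat("Fitted", x$method, "classifier on", x$n, "cases\n")
  invisible(x)
}

# argmax over a score matrix whose columns follow GROUP_LEVELS; ties go to the
# lower-ordered group.
score_to_label <- function(scores) {
  as_group(GROUP_LEVELS[max.col(scores, ties.method = "first")])
}

# ---------------------------------------------------------------------------
# Linear discriminant analysis, implemented from its classification-score
# form. For a single predictor with pooled within-group variance s2 the score
# of group k at x is
#   C_k(x) = c_k0 + c_k * x + log(n_k / N),
#   c_k = mu_k / s2,   c_k0 = -mu_k^2 / (2 * s2),
# and a case is assigned to the group with the largest score. The log-prior
# term shifts boundaries toward smaller groups.

#' Linear discriminant analysis for a single predictor
#'
#' @inheritParams fit_classifier
#' @return An object of class `c("mc_lda", "mc_fit")` with per-group constants
#'   `c0`, coefficients `c1`, log-priors and the pooled variance.
#' @export
fit_lda <- function(data) {
  tr <- training_frame(data)
  n_k <- table(tr$y)
  present <- names(n_k)[n_k > 0]
  if (length(present) < 2) stop_degenerate("fewer than 2 observed classes")
  if (any(n_k[present] < 2)) stop_degenerate("a class has fewer than 2 cases")
  N <- length(tr$x)
  mu <- c(tapply(tr$x, tr$y, mean))
  v <- c(tapply(tr$x, tr$y, var))
  s2 <- sum((n_k[present] - 1) * v[present]) / (N - length(present))
  if (!is.finite(s2) || s2 <= 0) stop_degenerate("zero pooled variance")
  structure(list(
    method = "LDA", n = N, classes = present,
    mu = mu, s2 = s2,
    c1 = mu / s2, c0 = -mu^2 / (2 * s2),
    log_prior = log(as.numeric(n_k) / N)[match(GROUP_LEVELS, names(n_k))]
  ), class = c("mc_lda", "mc_fit"))
}

#' Classification scores of a fitted LDA
#'
#' @param object A fitted `mc_lda`.
#' @param x Numeric predictor values.
#' @return Matrix of scores (columns A, B, C; `-Inf` for unobserved classes).
#' @export
lda_scores <- function(object, x) {
  scores <- matrix(-Inf, length(x), 3, dimnames = list(NULL, GROUP_LEVELS))
  for (k in object$classes) {
    i <- match(k, GROUP_LEVELS)
    scores[, i] <- object$c0[[k]] + object$c1[[k]] * x + object$log_prior[i]
  }
  scores
}

#' @export
predict.mc_lda <- function(object, newdata, ...) {
  score_to_label(lda_scores(object, newdata_x(newdata)))
}

# ---------------------------------------------------------------------------
# Quadratic discriminant analysis relaxes the pooled-variance constraint and
# gives each group its own variance; delegated to MASS.

#' Quadratic discriminant analysis
#'
#' @inheritParams fit_classifier
#' @return An object of class `c("mc_qda", "mc_fit")`.
#' @export
fit_qda <- function(data) {
  tr <- training_frame(data)
  y <- droplevels(tr$y)
  if (nlevels(y) < 2) stop_degenerate("fewer than 2 observed classes")
  v <- tapply(tr$x, y, var)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_degenerate("zero within-group variance")
  }
  fit <- MASS::qda(data.frame(x = tr$x), grouping = y)
  structure(list(method = "QDA", n = length(tr$x), fit = fit),
            class = c("mc_qda", "mc_fit"))
}

#' @export
predict.mc_qda <- function(object, newdata, ...) {
  post <- predict(object$fit, data.frame(x = newdata_x(newdata)))$posterior
  scores <- matrix(-Inf, nrow(post), 3, dimnames = list(NULL, GROUP_LEVELS))
  scores[, colnames(post)] <- post
  score_to_label(scores)
}

# ---------------------------------------------------------------------------
# Logistic regression: the binary logit extended to three classes as a
# multinomial model, fit by maximum likelihood.

#' Multinomial logistic regression
#'
#' @inheritParams fit_classifier
#' @return An object of class `c("mc_lr", "mc_fit")`.
#' @export
fit_lr <- function(data) {
  tr <- training_frame(data)
  y <- droplevels(tr$y)
  if (nlevels(y) < 2) stop_degenerate("fewer than 2 observed classes")
  df <- data.frame(x = tr$x, y = y)
  fit <- nnet::multinom(y ~ x, data = df, trace = FALSE, maxit = 200)
  structure(list(method = "LR", n = length(tr$x), fit = fit,
                 classes = levels(y)),
            class = c("mc_lr", "mc_fit"))
}

#' @export
predict.mc_lr <- function(object, newdata, ...) {
  x <- newdata_x(newdata)
  pr <- predict(object$fit, data.frame(x = x), type = "probs")
  scores <- matrix(-Inf, length(x), 3, dimnames = list(NULL, GROUP_LEVELS))
  if (is.matrix(pr)) {
    scores[, colnames(pr)] <- pr
  } else {
    # two observed classes: pr is P(second class)
    scores[, object$classes[1]] <- 1 - pr
    scores[, object$classes[2]] <- pr
  }
  score_to_label(scores)
}

# ---------------------------------------------------------------------------
# Generalized additive model: class log-odds are smooth functions of x,
# represented by a thin-plate regression spline with a fixed smoothing
# parameter (default 1.4). Very large lambda flattens the smooth toward the
# linear logistic fit.

#' Penalized-spline additive model classifier
#'
#' @inheritParams fit_classifier
#' @param lambda Fixed smoothing parameter applied to each smooth.
#' @return An object of class `c("mc_gam", "mc_fit")`.
#' @export
fit_gam <- function(data, lambda = 1.4) {
  stopifnot(lambda >= 0)
  tr <- training_frame(data)
  y <- droplevels(tr$y)
  if (nlevels(y) < 2) stop_degenerate("fewer than 2 observed classes")
  df <- data.frame(x = tr$x, y0 = as.integer(y) - 1L)
  if (nlevels(y) == 3) {
    fit <- mgcv::gam(list(y0 ~ s(x, sp = lambda), ~ s(x, sp = lambda)),
                     family = mgcv::multinom(K = 2), data = df)
  } else {
    fit <- mgcv::gam(y0 ~ s(x, sp = lambda), family = stats::binomial(),
                     data = df)
  }
  structure(list(method = "GAM", n = length(tr$x), fit = fit,
                 classes = levels(y), lambda = lambda),
            class = c("mc_gam", "mc_fit"))
}

#' @export
predict.mc_gam <- function(object, newdata, ...) {
  x <- newdata_x(newdata)
  scores <- matrix(-Inf, length(x), 3, dimnames = list(NULL, GROUP_LEVELS))
  pr <- predict(object$fit, data.frame(x = x), type = "response")
  if (length(object$classes) == 3) {
    scores[, object$classes] <- as.matrix(pr)
  } else {
    scores[, object$classes[1]] <- 1 - pr
    scores[, object$classes[2]] <- pr
  }
  score_to_label(scores)
}

# ---------------------------------------------------------------------------
# Neural network: one hidden layer, logistic activations, trained by
# back-propagation to minimize the penalized least-squares criterion
# sum_i (y_i - yhat_i)^2 + decay * ||w||^2 over the class-indicator targets.

#' Single-hidden-layer neural network classifier
#'
#' @inheritParams fit_classifier
#' @param hidden Number of hidden units.
#' @param decay Weight-decay penalty.
#' @param maxit Maximum training epochs.
#' @param restarts Refits from fresh random weights if training diverges.
#' @return An object of class `c("mc_nnet", "mc_fit")`.
#' @export
fit_nnet <- function(data, hidden = 5L, decay = 0.1, maxit = 500L,
                     restarts = 3L) {
  stopifnot(hidden >= 1, decay >= 0)
  tr <- training_frame(data)
  y <- droplevels(tr$y)
  if (nlevels(y) < 2) stop_degenerate("fewer than 2 observed classes")
  targets <- nnet::class.ind(y)
  for (attempt in seq_len(restarts)) {
    fit <- nnet::nnet(x = matrix(tr$x, ncol = 1), y = targets, size = hidden,
                      decay = decay, maxit = maxit, trace = FALSE)
    if (is.finite(fit$value)) break
  }
  if (!is.finite(fit$value)) stop_degenerate("network training diverged")
  structure(list(method = "NNET", n = length(tr$x), fit = fit,
                 classes = levels(y), loss = fit$value),
            class = c("mc_nnet", "mc_fit"))
}

#' @export
predict.mc_nnet <- function(object, newdata, ...) {
  x <- newdata_x(newdata)
  pr <- predict(object$fit, matrix(x, ncol = 1))
  scores <- matrix(-Inf, length(x), 3, dimnames = list(NULL, GROUP_LEVELS))
  scores[, object$classes] <- pr
  score_to_label(scores)
}
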