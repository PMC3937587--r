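# Mixture discriminant analysis: each observed group is modeled as a mixture
# of Gaussian subclasses rather than a single normal. Parameters (subclass
# means, mixing proportions, a common or group-specific variance) are
# estimated by EM on each group's cases; classification uses the group priors
# times the fitted mixture densities.

#' Mixture discriminant analysis via EM
#'
#' Fits a Gaussian mixture with `subclasses` components to each observed
#' group. The E-step computes subclass responsibilities within each group;
#' the M-step updates subclass means, within-group mixing proportions and the
#' variance (one variance pooled over everything, or one per group). The
#' conditional log-likelihood is non-decreasing over iterations; if the
#' change falls below `tol` the fit is converged, otherwise the best iterate
#' is returned with `converged = FALSE`. Subclass means are initialized by a
#' k-means partition of each group's predictor values (consumes the R RNG
#' stream).
#'
#' @inheritParams fit_classifier
#' @param subclasses Number of Gaussian subclasses per group (each observed
#'   group must have at least this many cases).
#' @param variance `"common"` or `"group"` subclass variance.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `c("mc_mixda", "mc_fit")` with per-group
#'   subclass means, mixing proportions, variances, priors, the
#'   log-likelihood trace and a convergence flag.
#' @examples
#' set.seed(2)
#' ds <- simulate_condition(sim_condition(topology("AB_BC"), 300, c(1, 1, 1),
#'                                        d = 0.8, pi = 0, seed = 5))
#' fit <- fit_mixda(ds, subclasses = 2)
#' all(diff(fit$loglik_trace) > -1e-8)
#' @export
fit_mixda <- function(data, subclasses = 3L, variance = c("common", "group"),
                      tol = 1e-6, max_iter = 500L) {
  variance <- match.arg(variance)
  stopifnot(subclasses >= 1)
  tr <- training_frame(data)
  y <- droplevels(tr$y)
  classes <- levels(y)
  if (length(classes) < 2) stop_degenerate("fewer than 2 observed classes")
  n_k <- table(y)
  if (any(n_k < subclasses)) {
    stop_degenerate("a class has fewer cases than requested subclasses")
  }
  N <- length(tr$x)
  xs <- split(tr$x, y)

  # k-means-style initialization per group
  w <- m <- list()
  s2g <- numeric(length(classes))
  names(s2g) <- classes
  for (g in classes) {
    xg <- xs[[g]]
    R <- min(subclasses, length(unique(xg)))
    if (R > 1) {
      km <- suppressWarnings(kmeans(xg, centers = R))
      ordc <- order(km$centers)
      m[[g]] <- as.numeric(km$centers[ordc])
      w[[g]] <- as.numeric(table(factor(km$cluster, levels = ordc))) /
        length(xg)
      s2g[g] <- max(km$tot.withinss / length(xg), 1e-6)
    } else {
      m[[g]] <- rep(mean(xg), subclasses)[1]
      w[[g]] <- 1
      s2g[g] <- max(var(xg) * (length(xg) - 1) / length(xg), 1e-6,
                    na.rm = TRUE)
    }
  }
  s2 <- if (variance == "common") {
    rep(sum(s2g * as.numeric(n_k)) / N, length(classes))
  } else {
    s2g
  }
  names(s2) <- classes

  loglik <- function() {
    ll <- 0
    for (gi in seq_along(classes)) {
      g <- classes[gi]
      dens <- sapply(seq_along(m[[g]]), function(r) {
        w[[g]][r] * dnorm(xs[[g]], m[[g]][r], sqrt(s2[g]))
      })
      if (!is.matrix(dens)) dens <- matrix(dens, nrow = 1)
      ll <- ll + sum(log(pmax(rowSums(dens), 1e-300)))
    }
    ll
  }

  trace <- loglik()
  best <- list(w = w, m = m, s2 = s2, ll = trace[1])
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ss_num <- 0
    for (g in classes) {
      xg <- xs[[g]]
      R <- length(m[[g]])
      dens <- sapply(seq_len(R), function(r) {
        w[[g]][r] * dnorm(xg, m[[g]][r], sqrt(s2[g]))
      })
      if (!is.matrix(dens)) dens <- matrix(dens, nrow = length(xg))
      resp <- dens / pmax(rowSums(dens), 1e-300)
      nr <- colSums(resp)
      w[[g]] <- pmax(nr, 1e-12) / length(xg)
      w[[g]] <- w[[g]] / sum(w[[g]])
      m[[g]] <- colSums(resp * xg) / pmax(nr, 1e-12)
      ssg <- sum(resp * outer(xg, m[[g]], "-")^2)
      if (variance == "group") {
        s2[g] <- max(ssg / length(xg), 1e-8)
      } else {
        ss_num <- ss_num + ssg
      }
    }
    if (variance == "common") s2[] <- max(ss_num / N, 1e-8)
    ll <- loglik()
    trace <- c(trace, ll)
    if (ll >= best$ll) best <- list(w = w, m = m, s2 = s2, ll = ll)
    if (abs(ll - trace[length(trace) - 1]) < tol * (abs(ll) + 1e-3)) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    method = "MIXDA", n = N, classes = classes,
    weights = best$w, means = best$m, sigma2 = best$s2,
    log_prior = setNames(log(as.numeric(n_k) / N), classes),
    variance = variance, loglik_trace = trace, converged = converged
  ), class = c("mc_mixda", "mc_fit"))
}

#' @export
predict.mc_mixda <- function(object, newdata, ...) {
  x <- newdata_x(newdata)
  scores <- matrix(-Inf, length(x), 3, dimnames = list(NULL, GROUP_LEVELS))
  for (g in object$classes) {
    dens <- sapply(seq_along(object$means[[g]]), function(r) {
      object$weights[[g]][r] * dnorm(x, object$means[[g]][r],
                                     sqrt(object$sigma2[g]))
    })
    if (!is.matrix(dens)) dens <- matrix(dens, nrow = length(x))
    scores[, g] <- object$log_prior[g] + log(pmax(rowSums(dens), 1e-300))
  }
  score_to_label(scores)
}

#' @export
print.mc_mixda <- function(x, ...) {
  cat(sprintf(
    "Mixture discriminant analysis: %d groups, %s variance, %sconverged\n",
    length(x$classes), x$variance, if (x$converged) "" else "NOT "))
  for (g in x$classes) {
    cat(sprintf("  %s: means (%s), weights (%s), var %.3f\n", g,
                paste(sprintf("%.3f", x$means[[g]]), collapse = ", "),
                paste(sprintf("%.2f", x$weights[[g]]), collapse = ", "),
                x$sigma2[g]))
  }
  invisible(x)
}
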