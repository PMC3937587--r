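# Independent reference implementations used as oracles. These are written
# in plain R, deliberately brute-force, and share no code with the package.

# Deviance of a node from the per-case multinomial log-likelihood: expand the
# counts into cases and sum individual log-probabilities at the MLE.
deviance_oracle <- function(counts) {
  cases <- rep(seq_along(counts), counts)
  p_hat <- counts / sum(counts)
  -2 * sum(log(p_hat[cases]))
}

# Reference deviance-splitting tree grower: returns ordered breaks and a
# prediction function. Same algorithm as the package (best split by summed
# child deviance, strict decrease, midpoint split values, in-order leaves)
# but built independently on unsorted data with naive scans.
ref_tree <- function(x, y, minsplit, minbucket) {
  dev <- function(yy) {
    n <- length(yy)
    if (n == 0) return(0)
    p <- table(factor(yy, levels = 1:3)) / n
    -2 * sum(ifelse(p > 0, table(factor(yy, levels = 1:3)) * log(p), 0))
  }
  grow <- function(x, y) {
    n <- length(x)
    if (n < minsplit || length(unique(y)) < 2) {
      return(list(leaf = TRUE, label = which.max(tabulate(y, 3))))
    }
    xs <- sort(unique(x))
    best <- dev(y) - 1e-9
    best_split <- NULL
    for (i in seq_len(length(xs) - 1)) {
      s <- (xs[i] + xs[i + 1]) / 2
      l <- y[x <= s]; r <- y[x > s]
      if (length(l) < minbucket || length(r) < minbucket) next
      d <- dev(l) + dev(r)
      if (d < best) { best <- d; best_split <- s }
    }
    if (is.null(best_split)) {
      return(list(leaf = TRUE, label = which.max(tabulate(y, 3))))
    }
    list(leaf = FALSE, split = best_split,
         left = grow(x[x <= best_split], y[x <= best_split]),
         right = grow(x[x > best_split], y[x > best_split]))
  }
  root <- grow(x, y)
  breaks <- c()
  walk <- function(nd) {
    if (nd$leaf) return(invisible())
    walk(nd$left); breaks <<- c(breaks, nd$split); walk(nd$right)
  }
  walk(root)
  predict1 <- function(v) {
    nd <- root
    while (!nd$leaf) nd <- if (v <= nd$split) nd$left else nd$right
    nd$label
  }
  list(breaks = breaks, predict = function(v) vapply(v, predict1, 0))
}

# Brute-force per-case tally of misclassification rates.
rates_oracle <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  g <- c("A", "B", "C")
  wrong <- integer(3); tot <- integer(3)
  for (i in seq_along(truth)) {
    k <- match(truth[i], g)
    tot[k] <- tot[k] + 1
    if (pred[i] != truth[i]) wrong[k] <- wrong[k] + 1
  }
  list(overall = sum(wrong) / sum(tot), group = wrong / tot)
}

# A quick equal-ratio three-group dataset for classifier tests.
make_dataset <- function(n = 150, d = 0.8, pi = 0, seed = 1,
                         ratio = c(1, 1, 1), top = "AB_BC") {
  simulate_condition(sim_condition(topology(top), n, ratio, d = d, pi = pi,
                                   seed = seed))
}
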