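# The eight classifiers and their contracts.

test_that("LDA scores reproduce the closed-form single-predictor case", {
  # engineered sample: exact means (0, 1, 2), exact pooled variance 1
  del <- 1 / sqrt(2)
  df <- data.frame(
    x = c(0 - del, 0 + del, 1 - del, 1 + del, 2 - del, 2 + del),
    label = rep(c("A", "B", "C"), each = 2))
  fit <- fit_lda(df)
  expect_equal(unname(fit$mu), c(0, 1, 2))
  expect_equal(fit$s2, 1)
  sc <- lda_scores(fit, 1.0)
  expect_equal(unname(sc[1, ]),
               c(log(1 / 3), 0.5 + log(1 / 3), log(1 / 3)))
  expect_equal(as.character(predict(fit, 1.0)), "B")
  # equal priors: nearest-mean rule
  expect_equal(as.character(predict(fit, c(-5, 0.49, 0.51, 5))),
               c("A", "A", "B", "C"))
})

test_that("log-prior terms shift LDA boundaries toward small groups", {
  del <- 1 / sqrt(2)
  df <- data.frame(
    x = c(rep(c(-del, del), 48) + 0, rep(c(-del, del), 12) + 1,
          rep(c(-del, del), 12) + 2),
    label = rep(c("A", "B", "C"), c(96, 24, 24)))
  fit <- fit_lda(df)
  gap <- fit$log_prior[1] - fit$log_prior[2]
  expect_equal(unname(gap), log(4))
  # A/B boundary: midpoint + s2 * log(nA/nB) / (muB - muA)
  s2 <- fit$s2
  b_ab <- 0.5 + s2 * log(4) / 1
  eps <- 1e-6
  expect_equal(as.character(predict(fit, c(b_ab - eps, b_ab + eps))),
               c("A", "B"))
})

test_that("LDA predictions coincide with the MASS reference", {
  set.seed(41)
  for (ratio in list(c(1, 1, 1), c(4, 1, 1), c(1, 4, 1))) {
    ds <- make_dataset(n = 300, d = 0.8, pi = 0.1, seed = sample.int(1e5, 1),
                       ratio = ratio)
    fit <- fit_lda(ds)
    ref <- MASS::lda(data.frame(x = ds$x),
                     grouping = factor(ds$observed_label))
    grid <- seq(min(ds$x), max(ds$x), length.out = 500)
    expect_identical(as.character(predict(fit, grid)),
                     as.character(predict(ref, data.frame(x = grid))$class))
  }
})

test_that("QDA nests LDA when group variances are equal", {
  set.seed(42)
  ds <- make_dataset(n = 1500, d = 0.8, seed = 5)
  agree <- mean(predict(fit_qda(ds), ds) == predict(fit_lda(ds), ds))
  expect_gt(agree, 0.95)
})

test_that("logistic regression separates separable groups and tracks LDA", {
  set.seed(43)
  wide <- make_dataset(n = 300, d = 10, seed = 6)
  expect_equal(mean(predict(fit_lr(wide), wide) != wide$observed_label), 0)

  diffs <- replicate(100, {
    ds <- make_dataset(n = 150, d = 0.8, seed = sample.int(1e6, 1))
    abs(mean(predict(fit_lr(ds), ds) != ds$true_label) -
        mean(predict(fit_lda(ds), ds) != ds$true_label))
  })
  expect_lt(mean(diffs), 0.02)
})

test_that("heavily smoothed GAM approaches the linear logistic fit", {
  set.seed(44)
  ds <- make_dataset(n = 450, d = 0.8, seed = 7)
  g <- fit_gam(ds, lambda = 1e7)
  lr <- fit_lr(ds)
  grid <- seq(min(ds$x), max(ds$x), length.out = 300)
  expect_gt(mean(predict(g, grid) == predict(lr, grid)), 0.95)
  # the study default is lambda = 1.4
  expect_equal(classifier_settings()$gam_lambda, 1.4)
  g14 <- fit_gam(ds)
  expect_equal(g14$lambda, 1.4)
  expect_false(anyNA(predict(g14, ds)))
})

test_that("the network fits separable data and collapses under heavy decay", {
  set.seed(45)
  wide <- make_dataset(n = 150, d = 10, seed = 8)
  fit <- fit_nnet(wide)
  expect_equal(mean(predict(fit, wide) != wide$observed_label), 0)
  expect_true(is.finite(fit$loss))

  skew <- make_dataset(n = 150, d = 0.8, ratio = c(25, 100, 25), seed = 9)
  crushed <- fit_nnet(skew, decay = 1e3)
  expect_true(all(predict(crushed, skew) == "B"))
})

test_that("MIXDA log-likelihood never decreases and recovers subclasses", {
  set.seed(46)
  for (s in 1:5) {
    ds <- make_dataset(n = 150, d = 0.5, pi = 0.2, seed = 50 + s)
    fit <- fit_mixda(ds, subclasses = 3)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
  }
  # two-lump class: subgroup means at +/- 2 recovered
  set.seed(47)
  xA <- c(rnorm(1000, -2), rnorm(1000, 2))
  xB <- rnorm(1000, 8)
  df <- data.frame(x = c(xA, xB), label = rep(c("A", "B"), c(2000, 1000)))
  fit <- fit_mixda(df, subclasses = 2)
  expect_equal(sort(fit$means[["A"]]), c(-2, 2), tolerance = 0.1 / 2)
})

test_that("MIXDA with one subclass and common variance matches LDA", {
  # exact degeneracy requires equal observed priors (the EM variance is the
  # ML estimate, so with unequal priors boundaries shift microscopically)
  set.seed(48)
  for (s in 1:50) {
    ds <- make_dataset(n = 150, d = 0.4 + (s %% 5) / 4, pi = 0,
                       seed = 500 + s)
    m <- fit_mixda(ds, subclasses = 1, variance = "common")
    l <- fit_lda(ds)
    expect_identical(as.character(predict(m, ds)),
                     as.character(predict(l, ds)))
  }
})

test_that("every method honours the uniform fit/predict contract", {
  set.seed(49)
  ds <- make_dataset(n = 150, d = 0.8, pi = 0.2, seed = 99)
  for (m in CLASSIFIER_METHODS) {
    set.seed(123)
    fit <- fit_classifier(m, ds, classifier_settings(rf_trees = 100))
    pr <- predict(fit, ds)
    expect_s3_class(fit, "mc_fit")
    expect_length(pr, 150)
    expect_false(anyNA(pr))
    expect_true(all(pr %in% c("A", "B", "C")))
  }
})

test_that("greater separation lowers training error for every method but RF", {
  set.seed(50)
  seeds <- c(301, 302, 303)
  for (m in setdiff(CLASSIFIER_METHODS, "RF")) {
    err <- function(d) {
      mean(vapply(seeds, function(s) {
        ds <- make_dataset(n = 150, d = d, pi = 0, seed = s)
        set.seed(s)
        fit <- fit_classifier(m, ds, classifier_settings(rf_trees = 100))
        mean(predict(fit, ds) != ds$true_label)
      }, 0))
    }
    expect_lt(err(1.6), err(0.2))
  }
})

test_that("degenerate fits are signalled, not silently wrong", {
  tiny <- data.frame(x = c(0, 1, 5, 5.1), label = c("A", "A", "B", "C"))
  expect_error(fit_lda(tiny), class = "mc_degenerate")
  const <- data.frame(x = c(rep(1, 5), rep(2, 5)),
                      label = rep(c("A", "B"), each = 5))
  expect_error(fit_qda(const), class = "mc_degenerate")
  one_class <- data.frame(x = rnorm(10), label = rep("A", 10))
  expect_error(fit_lr(one_class), class = "mc_degenerate")
  expect_error(fit_mixda(data.frame(x = rnorm(6),
                                    label = rep(c("A", "B"), 3)),
                         subclasses = 5),
               class = "mc_degenerate")
})
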