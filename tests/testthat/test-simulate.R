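# Synthetic-data generator: group assignment, predictor draws, boundary
# positions, calibration and noise injection.

test_that("assign_groups produces exact counts and rejects bad ratios", {
  set.seed(1)
  expect_equal(as.numeric(table(assign_groups(150, c(50, 50, 50)))),
               c(50, 50, 50))
  expect_equal(as.numeric(table(assign_groups(150, c(100, 25, 25)))),
               c(100, 25, 25))
  expect_equal(as.numeric(table(assign_groups(1500, c(25, 100, 25)))),
               c(250, 1000, 250))
  expect_error(assign_groups(100, c(1, 1, 1)), "whole group counts")
})

test_that("predictor draws match the stated means, cutpoints and moments", {
  lab0 <- factor(rep(c("A", "B", "C"), 5), levels = c("A", "B", "C"))
  ds0 <- generate_predictor(lab0, d = 0.8)
  expect_equal(unname(ds0$group_means), c(0, 0.8, 1.6))
  expect_equal(unname(ds0$cutpoints), c(0.4, 1.2))

  set.seed(42)
  labels <- factor(rep(c("A", "B", "C"), each = 1e5),
                   levels = c("A", "B", "C"))
  ds <- generate_predictor(labels, d = 0.5)
  mu <- tapply(ds$x, ds$true_label, mean)
  v <- tapply(ds$x, ds$true_label, var)
  expect_equal(as.numeric(diff(mu)), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(as.numeric(v), c(1, 1, 1), tolerance = 0.02)
})

test_that("boundary position is oriented to the near cut and uniform", {
  top <- topology("AB_BC")
  means <- c(0, 0.8, 1.6)
  # middle group at its own mean is farthest from both boundaries
  expect_equal(boundary_position(0.8, "B", top, means), 1)
  # top group at its own mean sits at its median
  expect_equal(boundary_position(1.6, "C", top, means), 0.5)
  # strict BC: group A has no boundary
  expect_true(is.na(boundary_position(0, "A", topology("BC",
              eligibility_mode = "strict"), means)))
  # small p near the relevant cut side
  expect_lt(boundary_position(0.79, "A", top, means),
            boundary_position(-1, "A", top, means))

  # probability integral transform: p ~ Uniform(0,1) within each group
  set.seed(7)
  for (g in c("A", "B", "C")) {
    x <- rnorm(1e5, means[match(g, c("A", "B", "C"))], 1)
    p <- boundary_position(x, g, top, means)
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }
})

test_that("calibration scalar has the closed form and matches Monte Carlo", {
  expect_equal(calibrate_scalar(0.5)$k, 1)
  expect_equal(calibrate_scalar(0.1)$k, 5)
  expect_equal(calibrate_scalar(0.25)$k, 2)
  expect_identical(calibrate_scalar(0)$k, Inf)
  expect_error(calibrate_scalar(0.6), "outside the design")

  set.seed(11)
  u <- runif(1e6)
  p <- runif(1e6)
  for (pi in c(0.1, 0.25, 0.3)) {
    k <- calibrate_scalar(pi)$k
    expect_equal(mean(u > k * p), pi, tolerance = 0.002 / pi)
  }
})

test_that("injection hits the target rate, non-differentially by group", {
  set.seed(3)
  cond <- sim_condition(topology("AB_BC"), 1.5e5, c(1, 1, 1), d = 0.8,
                        pi = 0.2, seed = 31)
  ds <- simulate_condition(cond)
  flip <- ds$observed_label != ds$true_label
  expect_equal(mean(flip), 0.2, tolerance = 0.004 / 0.2)
  per_group <- tapply(flip, ds$true_label, mean)
  expect_equal(as.numeric(per_group), rep(0.2, 3), tolerance = 0.01 / 0.2)

  # calibration holds at each design pi within 3 binomial SEs
  for (pi in c(0.1, 0.2, 0.3)) {
    dsi <- simulate_condition(sim_condition(topology("AB_BC"), 99999,
                                            c(1, 1, 1), d = 0.5, pi = pi,
                                            seed = 100 + pi * 10))
    f <- mean(dsi$observed_label != dsi$true_label)
    expect_lt(abs(f - pi), 3 * sqrt(pi * (1 - pi) / 99999))
  }
})

test_that("pi = 0 injects nothing and strict BC never touches group A", {
  ds <- simulate_condition(sim_condition(topology("AB_BC"), 1500, c(1, 1, 1),
                                         d = 0.5, pi = 0, seed = 5))
  expect_identical(ds$observed_label, ds$true_label)

  ds2 <- simulate_condition(sim_condition(
    topology("BC", eligibility_mode = "strict"), 9e4, c(1, 1, 1),
    d = 0.2, pi = 0.3, seed = 6))
  a <- ds2$true_label == "A"
  expect_identical(ds2$observed_label[a], ds2$true_label[a])
})

test_that("flips never cross the forbidden A/C confusion", {
  # ~1e6 cases across topologies and modes at the heaviest noise level
  set.seed(8)
  for (topn in c("BC", "AB_BC")) for (mode in c("strict", "uniform")) {
    ds <- simulate_condition(sim_condition(
      topology(topn, eligibility_mode = mode), 249999,
      c(1, 1, 1), d = 0.2, pi = 0.3, seed = mix_ <- sample.int(1e6, 1)))
    ac <- (ds$true_label == "A" & ds$observed_label == "C") |
      (ds$true_label == "C" & ds$observed_label == "A")
    expect_equal(sum(ac), 0)
  }
})

test_that("flips concentrate on cases improbable for their own group", {
  # "boundary-proximal" is probabilistic: a case flips when it sits far out
  # on the side of its group's distribution that faces the confusable
  # neighbour, i.e. has a small boundary position. (Metric distance to the
  # cut-point is not monotone in that probability for cases beyond the cut.)
  top <- topology("AB_BC")
  ds <- simulate_condition(sim_condition(top, 99999, c(1, 1, 1),
                                         d = 0.8, pi = 0.3, seed = 9))
  flip <- ds$observed_label != ds$true_label
  p <- boundary_position(ds$x, ds$true_label, top, ds$group_means)
  for (g in c("A", "B", "C")) {
    sel <- ds$true_label == g
    expect_lt(mean(p[sel & flip]), mean(p[sel & !flip]))
    # flipped cases sit farther from their own group mean
    dist_mean <- abs(ds$x - ds$group_means[match(g, c("A", "B", "C"))])
    expect_gt(mean(dist_mean[sel & flip]), mean(dist_mean[sel & !flip]))
  }
  # among cases still on their own side of the cut, flips are nearer the cut
  a_side <- ds$true_label == "A" & ds$x <= ds$cutpoints[1]
  expect_lt(mean((ds$cutpoints[1] - ds$x)[a_side & flip]),
            mean((ds$cutpoints[1] - ds$x)[a_side & !flip]))
})

test_that("simulation is deterministic given the condition seed", {
  cond <- sim_condition(topology("BC"), 150, c(25, 25, 100), d = 1.6,
                        pi = 0.3, seed = 77)
  d1 <- simulate_condition(cond)
  d2 <- simulate_condition(cond)
  expect_identical(d1, d2)
})

test_that("datasets round-trip through CSV", {
  ds <- simulate_condition(sim_condition(topology("AB_BC"), 90, c(1, 1, 1),
                                         d = 0.8, pi = 0.2, seed = 12))
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f)
  expect_equal(back$x, ds$x)
  expect_identical(back$true_label, ds$true_label)
  expect_identical(back$observed_label, ds$observed_label)
  unlink(f)
})
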