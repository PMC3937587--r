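#' Define a misclassification topology
#'
#' A topology says which pairs of groups can be confused when label noise is
#' injected. Two topologies are studied: `"BC"`, where confusion happens only
#' between the two upper groups, and `"AB_BC"`, where any pair of *adjacent*
#' groups can be confused. The extreme pair A/C is never confusable: groups
#' fall along a continuum and errors happen across the shared cut-point of
#' adjacent groups only.
#'
#' @param name `"BC"` or `"AB_BC"`.
#' @param eligibility_mode `"strict"` or `"uniform"`. In strict mode a group
#'   with no allowed confusion (group A under `"BC"`) is never flipped; in
#'   uniform mode every case is flip-eligible and a flipped case moves to its
#'   nearest adjacent group (so A can move to B even under `"BC"`). Uniform is
#'   the default: it makes the injected error non-differential across all three
#'   groups under both topologies.
#' @return An object of class `mc_topology` with elements `name`,
#'   `allowed_confusions` (list of unordered group pairs) and
#'   `eligibility_mode`.
#' @examples
#' topology("BC")
#' topology("AB_BC", eligibility_mode = "strict")
#' @export
topology <- function(name = c("AB_BC", "BC"),
                     eligibility_mode = c("uniform", "strict")) {
  name <- match.arg(name)
  eligibility_mode <- match.arg(eligibility_mode)
  allowed <- switch(name,
    BC = list(c("B", "C")),
    AB_BC = list(c("A", "B"), c("B", "C"))
  )
  structure(
    list(name = name, allowed_confusions = allowed,
         eligibility_mode = eligibility_mode),
    class = "mc_topology"
  )
}

#' @export
print.mc_topology <- function(x, ...) {
  pairs <- vapply(x$allowed_confusions, paste, "", collapse = "<->")
  cat("Misclassification topology", x$name, "\n")
  cat("  allowed confusions:", paste(pairs, collapse = ", "), "\n")
  cat("  eligibility mode:  ", x$eligibility_mode, "\n")
  invisible(x)
}

#' Describe one simulation condition
#'
#' A condition is one cell of the crossed design: a topology, a total sample
#' size, a group-size ratio, a separation between adjacent group means, a
#' target misclassification proportion, and a seed.
#'
#' @param topology An [topology()] object (or a topology name).
#' @param n_total Total sample size (the study uses 150 and 1500).
#' @param ratio Length-3 vector of relative group sizes, e.g. `c(25, 100, 25)`;
#'   scaled to sum to `n_total` (the scaled counts must be whole numbers).
#' @param d Standardized mean difference between adjacent group means
#'   (within-group SD is 1, so `d` is Cohen's d between neighbours).
#' @param pi Target misclassification proportion among flip-eligible cases,
#'   in `[0, 0.5]` (the study uses 0, 0.1, 0.2, 0.3).
#' @param seed Integer seed; `simulate_condition()` is deterministic given it.
#' @return An object of class `mc_condition`.
#' @examples
#' sim_condition(topology("AB_BC"), 150, c(50, 50, 50), d = 0.8, pi = 0.2)
#' @export
sim_condition <- function(topology, n_total, ratio, d, pi, seed = 1L) {
  if (is.character(topology)) topology <- topology(topology)
  stopifnot(inherits(topology, "mc_topology"),
            length(ratio) == 3, all(ratio > 0),
            d > 0, pi >= 0, pi <= 0.5, n_total >= 3)
  counts <- ratio / sum(ratio) * n_total
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("ratio ", paste(ratio, collapse = ":"),
         " does not scale to whole group counts at n_total = ", n_total)
  }
  structure(
    list(topology = topology, n_total = as.integer(n_total),
         ratio = as.numeric(ratio), d = d, pi = pi, seed = as.integer(seed)),
    class = "mc_condition"
  )
}

#' @export
print.mc_condition <- function(x, ...) {
  cat(sprintf(
    "Simulation condition: %s, n = %d, ratio %s, d = %g, pi = %g, seed = %d\n",
    x$topology$name, x$n_total, paste(x$ratio, collapse = ":"), x$d, x$pi,
    x$seed))
  invisible(x)
}

#' Assign true group labels for a sample-size ratio
#'
#' Scales the ratio to counts summing to `n_total` and returns the labels in
#' random order.
#'
#' @inheritParams sim_condition
#' @return Factor of length `n_total` with levels `A`, `B`, `C`.
#' @examples
#' table(assign_groups(150, c(100, 25, 25)))
#' @export
assign_groups <- function(n_total, ratio) {
  counts <- ratio / sum(ratio) * n_total
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("ratio does not scale to whole group counts at n_total = ", n_total)
  }
  counts <- round(counts)
  sample(as_group(rep(GROUP_LEVELS, counts)))
}

#' Draw the predictor for labelled cases
#'
#' Each case's predictor value is drawn from a unit-variance normal whose mean
#' depends on its group: means are `(0, d, 2d)` so that adjacent groups differ
#' by `d` standard deviations. The artificial cut-points separating adjacent
#' groups sit at the midpoints of adjacent means, `d/2` and `3d/2`.
#'
#' @param labels Factor of true group labels (levels `A`, `B`, `C`).
#' @param d Adjacent-group standardized mean difference, `d > 0`.
#' @return A `mc_dataset` with the predictor `x`, `true_label`,
#'   `observed_label` (initially equal to `true_label`), `group_means` and
#'   `cutpoints`.
#' @examples
#' ds <- generate_predictor(assign_groups(150, c(1, 1, 1)), d = 0.8)
#' ds$group_means
#' @export
generate_predictor <- function(labels, d) {
  stopifnot(d > 0)
  labels <- as_group(labels)
  means <- c(A = 0, B = d, C = 2 * d)
  x <- rnorm(length(labels), mean = means[as.integer(labels)], sd = 1)
  structure(
    list(x = x, true_label = labels, observed_label = labels,
         group_means = means, cutpoints = c(AB = d / 2, BC = 3 * d / 2),
         d = d, pi = 0, topology = NULL),
    class = "mc_dataset"
  )
}

#' @export
print.mc_dataset <- function(x, ...) {
  flips <- sum(x$observed_label != x$true_label)
  cat(sprintf("Labelled dataset: n = %d, d = %g, means (%g, %g, %g)\n",
              length(x$x), x$d, x$group_means[1], x$group_means[2],
              x$group_means[3]))
  cat(sprintf("  true counts %s; %d observed labels differ from truth\n",
              paste(table(x$true_label), collapse = "/"), flips))
  invisible(x)
}

#' @export
as.data.frame.mc_dataset <- function(x, ...) {
  data.frame(case_id = seq_along(x$x), x = x$x,
             true_group = as.integer(x$true_label),
             observed_group = as.integer(x$observed_label))
}

#' Boundary position of a case within its group
#'
#' The flip probability of a case must be highest near the artificial
#' cut-point(s) of its group. This function maps each case to a position
#' `p` in `[0, 1]` that is small near the relevant cut-point side and — by the
#' probability integral transform — exactly Uniform(0,1) over the group's
#' predictor distribution. With `F_g` the within-group normal CDF: a group
#' whose only allowed confusion lies above it gets `p = 1 - F_g(x)`; below it,
#' `p = F_g(x)`; a middle group confusable on both sides gets
#' `p = 2 * min(F_g(x), 1 - F_g(x))`. Uniformity is what makes the calibration
#' scalar of [calibrate_scalar()] exact.
#'
#' @param x Numeric predictor values.
#' @param g Group labels (single level or vector matching `x`).
#' @param topology An [topology()] object.
#' @param means Named or positional length-3 vector of group means.
#' @return Numeric vector of positions in `[0, 1]`; `NA` for cases whose group
#'   is not flip-eligible under a strict topology (the "no position" signal).
#' @examples
#' top <- topology("AB_BC")
#' boundary_position(0.8, "B", top, means = c(0, 0.8, 1.6))  # at own mean: 1
#' @export
boundary_position <- function(x, g, topology, means) {
  g <- as_group(rep_len(g, length(x)))
  means <- as.numeric(means)
  Fg <- pnorm(x, mean = means[as.integer(g)], sd = 1)
  dir <- flip_direction(g, topology)
  p <- rep(NA_real_, length(x))
  p[dir == "up"] <- 1 - Fg[dir == "up"]
  p[dir == "down"] <- Fg[dir == "down"]
  both <- dir == "both"
  p[both] <- 2 * pmin(Fg[both], 1 - Fg[both])
  p
}

# For each case, which side its allowed confusion lies on: "up", "down",
# "both", or "none" (strict-mode ineligible).
flip_direction <- function(g, topology) {
  g <- as_group(g)
  dir <- rep("none", length(g))
  if (topology$name == "AB_BC") {
    dir[g == "A"] <- "up"
    dir[g == "B"] <- "both"
    dir[g == "C"] <- "down"
  } else { # BC
    dir[g == "B"] <- "up"
    dir[g == "C"] <- "down"
    if (topology$eligibility_mode == "uniform") dir[g == "A"] <- "up"
  }
  dir
}

#' Calibration scalar for a target misclassification proportion
#'
#' A case flips when an independent Uniform(0,1) draw `u` exceeds `k * p`,
#' where `p` is its boundary position. Because `p` is itself Uniform(0,1)
#' within each eligible group, the expected flip fraction is
#' `P(U > kP) = 1/(2k)`, so the scalar achieving a target proportion `pi` is
#' `k = 1/(2*pi)`. With no scalar adjustment (`k = 1`) about half of all
#' eligible cases flip.
#'
#' @param target_pi Target flip proportion among eligible cases, in `(0, 0.5]`;
#'   `0` returns the no-injection sentinel `k = Inf`.
#' @return An object of class `mc_calibration` with elements `k` and
#'   `target_pi`.
#' @examples
#' calibrate_scalar(0.1)$k   # 5
#' calibrate_scalar(0.5)$k   # 1
#' @export
calibrate_scalar <- function(target_pi) {
  stopifnot(target_pi >= 0)
  if (target_pi > 0.5) {
    stop("target_pi > 0.5 is outside the design (k would be < 1)")
  }
  k <- if (target_pi == 0) Inf else 1 / (2 * target_pi)
  structure(list(k = k, target_pi = target_pi), class = "mc_calibration")
}

#' @export
print.mc_calibration <- function(x, ...) {
  cat(sprintf("Calibration scalar k = %g for target proportion %g\n",
              x$k, x$target_pi))
  invisible(x)
}

#' Inject systematic boundary-proximal label noise
#'
#' For each flip-eligible case a Uniform(0,1) number `u` is drawn and compared
#' with the scaled boundary position `k * p`: the case's observed label flips
#' when `u > k * p`, so cases close to a cut-point (small `p`) are the most
#' likely to be mislabeled, and the expected flip fraction among eligible
#' cases equals `pi`. A flipped case is reassigned to the group for which it
#' has the next-highest probability of membership: A to B, C to B, and B to A
#' below its own mean or to C above it (under `"BC"`, B always moves to C).
#' The A/C confusion never occurs.
#'
#' @param ds A `mc_dataset` from [generate_predictor()].
#' @param topology An [topology()] object.
#' @param pi Target misclassification proportion in `[0, 0.5]`.
#' @return The dataset with `observed_label` filled in and `pi`/`topology`
#'   recorded.
#' @examples
#' set.seed(1)
#' ds <- generate_predictor(assign_groups(300, c(1, 1, 1)), d = 0.8)
#' ds <- inject_misclassification(ds, topology("AB_BC"), pi = 0.2)
#' mean(ds$observed_label != ds$true_label)
#' @export
inject_misclassification <- function(ds, topology, pi) {
  stopifnot(inherits(ds, "mc_dataset"))
  ds$pi <- pi
  ds$topology <- topology
  ds$observed_label <- ds$true_label
  if (pi == 0) {
    return(ds)
  }
  k <- calibrate_scalar(pi)$k
  dir <- flip_direction(ds$true_label, topology)
  p <- boundary_position(ds$x, ds$true_label, topology, ds$group_means)
  u <- runif(length(ds$x))
  flip <- dir != "none" & u > k * p
  dest <- destination_group(ds$true_label, ds$x, topology, ds$group_means)
  obs <- ds$observed_label
  obs[flip] <- dest[flip]
  ds$observed_label <- obs
  ds
}

destination_group <- function(g, x, topology, means) {
  g <- as_group(g)
  dest <- g
  if (topology$name == "AB_BC") {
    dest[g == "A"] <- "B"
    dest[g == "C"] <- "B"
    b <- g == "B"
    dest[b & x < means[2]] <- "A"
    dest[b & x >= means[2]] <- "C"
  } else {
    dest[g == "B"] <- "C"
    dest[g == "C"] <- "B"
    if (topology$eligibility_mode == "uniform") dest[g == "A"] <- "B"
  }
  dest
}

#' Simulate one design cell
#'
#' Composes [assign_groups()], [generate_predictor()] and
#' [inject_misclassification()] under the condition's seed, so the same
#' condition always yields the identical dataset.
#'
#' @param cond A [sim_condition()] object.
#' @return A `mc_dataset`.
#' @examples
#' cond <- sim_condition(topology("AB_BC"), 150, c(1, 1, 1), d = 0.8,
#'                       pi = 0.3, seed = 42)
#' ds <- simulate_condition(cond)
#' table(truth = ds$true_label, observed = ds$observed_label)
#' @export
simulate_condition <- function(cond) {
  stopifnot(inherits(cond, "mc_condition"))
  set.seed(cond$seed)
  labels <- assign_groups(cond$n_total, cond$ratio)
  ds <- generate_predictor(labels, cond$d)
  inject_misclassification(ds, cond$topology, cond$pi)
}

#' Write or read a labelled dataset as CSV
#'
#' Columns: `case_id`, `x`, `true_group`, `observed_group` with groups encoded
#' 1/2/3.
#'
#' @param ds A `mc_dataset`.
#' @param file Path to a CSV file.
#' @return `read_dataset_csv()` returns a `mc_dataset` (without generator
#'   metadata such as cut-points, which are not stored in the CSV).
#' @export
write_dataset_csv <- function(ds, file) {
  write.csv(as.data.frame(ds), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(file) {
  df <- read.csv(file)
  stopifnot(all(c("x", "true_group", "observed_group") %in% names(df)))
  structure(
    list(x = df$x, true_label = as_group(df$true_group),
         observed_label = as_group(df$observed_group),
         group_means = NULL, cutpoints = NULL, d = NA_real_, pi = NA_real_,
         topology = NULL),
    class = "mc_dataset"
  )
}
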