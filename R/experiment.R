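# The crossed Monte Carlo experiment: simulate every design cell, fit every
# requested classifier on the observed (noisy) labels, score the training
# cases against the true labels, and summarize marginal rates.

#' Define the crossed design grid
#'
#' The study's full design crosses 2 topologies x 2 sample sizes x 4 ratios x
#' 4 separations x 4 misclassification proportions (256 cells) with 1000
#' replications per cell. All levels and the replication count can be
#' restricted for desk-scale runs.
#'
#' @param topologies Character vector of topology names.
#' @param n_total Total sample sizes.
#' @param ratios List of length-3 group-size ratios.
#' @param d Adjacent-group standardized mean differences.
#' @param pi Misclassification proportions.
#' @param replications Replications per cell.
#' @param seed Master seed; every (cell, replication) gets its own derived
#'   stream, and each classifier fit a further derived stream.
#' @param eligibility_mode Passed to [topology()].
#' @return An object of class `mc_grid`.
#' @examples
#' design_grid(replications = 2)$n_cells
#' @export
design_grid <- function(topologies = c("BC", "AB_BC"),
                        n_total = c(150, 1500),
                        ratios = list(c(50, 50, 50), c(25, 25, 100),
                                      c(25, 100, 25), c(100, 25, 25)),
                        d = c(0.2, 0.5, 0.8, 1.6),
                        pi = c(0, 0.1, 0.2, 0.3),
                        replications = 1000L,
                        seed = 1L,
                        eligibility_mode = "uniform") {
  cells <- expand.grid(
    topology = topologies,
    n_total = n_total,
    ratio = vapply(ratios, paste, "", collapse = ":"),
    d = d,
    pi = pi,
    stringsAsFactors = FALSE
  )
  structure(list(cells = cells, ratios = ratios,
                 replications = as.integer(replications),
                 seed = as.integer(seed),
                 eligibility_mode = eligibility_mode,
                 n_cells = nrow(cells)),
            class = "mc_grid")
}

#' @export
print.mc_grid <- function(x, ...) {
  cat(sprintf("Design grid: %d cells x %d replications (master seed %d)\n",
              x$n_cells, x$replications, x$seed))
  invisible(x)
}

parse_ratio <- function(s) as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])

#' Run the crossed experiment
#'
#' For every design cell and replication, simulates a dataset, fits each
#' requested method on the observed labels, predicts the training cases and
#' scores them against the reference labels. Deterministic given the grid's
#' master seed. A degenerate fit is recorded as a row of `NA` rates rather
#' than aborting the run.
#'
#' @param grid A [design_grid()].
#' @param methods Character vector of classifier names (subset of
#'   [CLASSIFIER_METHODS]).
#' @param settings A [classifier_settings()].
#' @param reference `"truth"` (score against the true, pre-noise labels; the
#'   study's protocol) or `"observed"`.
#' @param progress Print one line per cell.
#' @return A `data.frame` of class `mc_results` with one row per
#'   (method, cell, replication): design descriptors, `overall` and per-group
#'   rates `g1`, `g2`, `g3`.
#' @examples
#' g <- design_grid(topologies = "AB_BC", n_total = 150,
#'                  ratios = list(c(1, 1, 1)), d = 0.8, pi = 0.2,
#'                  replications = 2, seed = 9)
#' run_design(g, methods = "LDA")
#' @export
run_design <- function(grid, methods = CLASSIFIER_METHODS,
                       settings = classifier_settings(),
                       reference = c("truth", "observed"),
                       progress = FALSE) {
  reference <- match.arg(reference)
  methods <- vapply(methods, function(m) {
    match.arg(toupper(m), CLASSIFIER_METHODS)
  }, "")
  cells <- grid$cells
  R <- grid$replications
  n_rows <- nrow(cells) * R * length(methods)
  out <- vector("list", n_rows)
  cell_secs <- numeric(nrow(cells))
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    t0 <- proc.time()[3]
    top <- topology(cell$topology, eligibility_mode = grid$eligibility_mode)
    for (rep_i in seq_len(R)) {
      cond <- sim_condition(top, cell$n_total, parse_ratio(cell$ratio),
                            d = cell$d, pi = cell$pi,
                            seed = mix_seed(grid$seed, ci, rep_i))
      ds <- simulate_condition(cond)
      ref <- if (reference == "truth") ds$true_label else ds$observed_label
      for (mi in seq_along(methods)) {
        set.seed(mix_seed(cond$seed, 1000L + mi))
        rates <- tryCatch({
          fit <- fit_classifier(methods[mi], ds, settings)
          misclassification_rates(predict(fit, ds), ref)
        }, mc_degenerate = function(e) NULL)
        row <- row + 1L
        out[[row]] <- c(
          if (is.null(rates)) rep(NA_real_, 4) else
            c(rates$overall, rates$group),
          ci, rep_i, mi)
      }
    }
    cell_secs[ci] <- proc.time()[3] - t0
    if (progress) {
      message(sprintf("cell %d/%d (%s n=%d %s d=%g pi=%g) in %.1fs",
                      ci, nrow(cells), cell$topology, cell$n_total,
                      cell$ratio, cell$d, cell$pi, cell_secs[ci]))
    }
  }
  mat <- do.call(rbind, out)
  res <- data.frame(
    method = methods[mat[, 7]],
    topology = cells$topology[mat[, 5]],
    n_total = cells$n_total[mat[, 5]],
    ratio = cells$ratio[mat[, 5]],
    d = cells$d[mat[, 5]],
    pi = cells$pi[mat[, 5]],
    rep = mat[, 6],
    overall = mat[, 1], g1 = mat[, 2], g2 = mat[, 3], g3 = mat[, 4],
    stringsAsFactors = FALSE
  )
  class(res) <- c("mc_results", "data.frame")
  attr(res, "cell_seconds") <- data.frame(cells, seconds = cell_secs)
  res
}

#' Marginal rate table over one design factor
#'
#' Mean per-group (and overall) misclassification rates for each method at
#' each level of one design factor, averaged over all retained rows — the
#' layout of the study's marginal summary tables.
#'
#' @param rt A results table from [run_design()].
#' @param factor One of `"pi"`, `"ratio"`, `"d"`, `"n_total"`, `"topology"`,
#'   `"method"`.
#' @param filter Optional named list restricting cells, e.g.
#'   `list(topology = "AB_BC", pi = 0.1)`.
#' @return A data.frame with columns `method`, `level`, `g1`, `g2`, `g3`,
#'   `overall`, `n_rows`.
#' @export
marginal_table <- function(rt, factor = "pi", filter = NULL) {
  stopifnot(factor %in% c("pi", "ratio", "d", "n_total", "topology",
                          "method"))
  keep <- rep(TRUE, nrow(rt))
  for (nm in names(filter)) {
    keep <- keep & rt[[nm]] %in% filter[[nm]]
  }
  rt <- rt[keep, , drop = FALSE]
  if (nrow(rt) == 0) stop("filter removed every result row")
  key <- if (factor == "method") list(method = rt$method) else
    list(method = rt$method, level = rt[[factor]])
  agg <- aggregate(rt[c("g1", "g2", "g3", "overall")], by = key,
                   FUN = mean, na.rm = TRUE)
  counts <- aggregate(list(n_rows = rt$g1), by = key, FUN = length)
  out <- merge(agg, counts, sort = TRUE)
  out[order(out$method, if (factor == "method") out$method else out$level), ]
}

#' Write or read an experiment results table as CSV
#'
#' A `# misclassim` comment line stamps the file with a label (typically the
#' configuration hash and seed); `read_results_csv()` skips it.
#'
#' @param rt Results table.
#' @param file CSV path.
#' @param stamp Optional character stamp recorded in the header comment.
#' @export
write_results_csv <- function(rt, file, stamp = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# misclassim results", stamp %||% ""), con)
  write.csv(rt, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(file) {
  res <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  class(res) <- c("mc_results", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
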