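# Repeated-measures ANOVA screen. Each simulated dataset (one cell x
# replication) is scored by every method, so "method" is a within-subject
# factor with the dataset as the subject; the design factors are
# between-subject. Classical univariate sums-of-squares decomposition with
# two error strata:
#   * between terms tested against the subject-within-cells mean square,
#   * terms involving method tested against the method-x-subject residual.
# Effect size is classical eta-squared, SS_term / SS_total.

#' Repeated-measures ANOVA of misclassification rates
#'
#' @param rt A balanced results table from [run_design()] (every subject —
#'   one simulated dataset — scored by every method, equal replications per
#'   cell).
#' @param outcome `"overall"`, `"g1"`, `"g2"` or `"g3"`.
#' @param between Design columns treated as between-subject factors.
#' @return A data.frame of class `mc_anova`: one row per term with `SS`,
#'   `df_num`, `df_den`, `F`, `p`, `eta_sq` and `stratum`, plus the two
#'   residual rows.
#' @examples
#' g <- design_grid(topologies = "AB_BC", n_total = 150,
#'                  ratios = list(c(1, 1, 1)), d = c(0.2, 1.6), pi = c(0, 0.3),
#'                  replications = 3, seed = 11)
#' rt <- run_design(g, methods = c("LDA", "CART"))
#' repeated_anova(rt, "overall", between = c("d", "pi"))
#' @export
repeated_anova <- function(rt, outcome = c("overall", "g1", "g2", "g3"),
                           between = c("n_total", "ratio", "pi", "d")) {
  outcome <- match.arg(outcome)
  between <- between[vapply(between, function(b) {
    length(unique(rt[[b]])) > 1
  }, TRUE)]
  if (length(between) == 0) stop("no between factor with > 1 level")
  y <- rt[[outcome]]
  if (anyNA(y)) stop("outcome contains NA rates; drop incomplete cells first")

  df <- data.frame(y = y, method = factor(rt$method))
  for (b in between) df[[b]] <- factor(rt[[b]])
  # subject = one simulated dataset: every design column + replication
  subj_cols <- c("topology", "n_total", "ratio", "pi", "d", "rep")
  subj_cols <- subj_cols[subj_cols %in% names(rt)]
  subject <- interaction(rt[subj_cols], drop = TRUE)
  cell <- interaction(rt[setdiff(subj_cols, "rep")], drop = TRUE)

  K <- nlevels(df$method)
  per_subj <- table(subject)
  if (length(unique(per_subj)) != 1 || unique(per_subj) != K) {
    stop("unbalanced input: every subject must be scored by every method")
  }
  per_cell <- table(cell)
  if (length(unique(per_cell)) != 1) {
    stop("unbalanced input: unequal replications across cells")
  }
  if (as.integer(per_cell[1]) / K < 2) {
    stop("at least 2 replications per cell are needed to estimate the ",
         "between-subject error stratum")
  }

  form <- as.formula(paste(
    "y ~ (", paste(between, collapse = " * "), ") * method"))
  tab <- anova(lm(form, data = df))  # balanced => orthogonal Type-I SS
  terms_tab <- tab[rownames(tab) != "Residuals", , drop = FALSE]

  ss_total <- sum((y - mean(y))^2)
  # between-subject residual: subjects within cells, aggregated over methods
  subj_mean <- tapply(y, subject, mean)
  cell_of_subj <- tapply(as.character(cell), subject, `[`, 1)
  cell_mean <- tapply(y, cell, mean)
  ss_subj <- K * sum((subj_mean - cell_mean[cell_of_subj])^2)
  n_cells <- nlevels(cell)
  reps <- as.integer(unique(per_cell)) / K
  df_subj <- n_cells * (reps - 1)
  ss_within_res <- ss_total - sum(terms_tab$`Sum Sq`) - ss_subj
  df_within_res <- df_subj * (K - 1)

  is_within <- grepl("(^|:)method(:|$)", rownames(terms_tab))
  ms_err <- ifelse(is_within,
                   ss_within_res / max(df_within_res, 1),
                   ss_subj / max(df_subj, 1))
  df_err <- ifelse(is_within, df_within_res, df_subj)
  ss <- terms_tab$`Sum Sq`
  dfn <- terms_tab$Df
  Fv <- ifelse(ss == 0, 0, (ss / dfn) / ms_err)
  pv <- ifelse(ss == 0, 1, pf(Fv, dfn, df_err, lower.tail = FALSE))
  eta <- if (ss_total > 0) ss / ss_total else rep(0, length(ss))

  out <- data.frame(
    term = rownames(terms_tab),
    SS = ss, df_num = dfn, df_den = df_err, F = Fv, p = pv, eta_sq = eta,
    stratum = ifelse(is_within, "within", "between"),
    stringsAsFactors = FALSE
  )
  res <- data.frame(
    term = c("Residuals (subjects)", "Residuals (within)"),
    SS = c(ss_subj, ss_within_res), df_num = c(df_subj, df_within_res),
    df_den = NA, F = NA, p = NA,
    eta_sq = if (ss_total > 0) c(ss_subj, ss_within_res) / ss_total else
      c(0, 0),
    stratum = c("between", "within"), stringsAsFactors = FALSE
  )
  out <- rbind(out, res)
  rownames(out) <- NULL
  attr(out, "ss_total") <- ss_total
  class(out) <- c("mc_anova", "data.frame")
  out
}

#' @export
print.mc_anova <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANOVA (method = within-subject factor)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Flag important ANOVA terms
#'
#' The study's importance rule: a term matters when it is statistically
#' significant *and* explains at least 10% of the total variation.
#'
#' @param effects A `mc_anova` table (or any data.frame with `p` and
#'   `eta_sq`).
#' @param alpha Significance level.
#' @param eta_min Minimum eta-squared.
#' @return The flagged subset, same columns.
#' @examples
#' flag_important(data.frame(term = "pi", p = 1e-5, eta_sq = 0.45))
#' @export
flag_important <- function(effects, alpha = 0.05, eta_min = 0.1) {
  keep <- !is.na(effects$p) & effects$p < alpha & effects$eta_sq >= eta_min
  effects[keep, , drop = FALSE]
}
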