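#' Nonparametric group statistics for pulse-parameter cohorts
#'
#' The group layer mirrors the study design: omnibus Kruskal-Wallis across
#' the four diagnostic groups, pairwise Mann-Whitney of each patient group
#' against the normal group with Bonferroni correction, Spearman rank
#' correlation of parameters with RNFL thickness, OLS regression slopes,
#' and a repeated-measures coefficient of variation.
#'
#' @name cohort-statistics
NULL

.check_cohort <- function(table, parameter) {
  if (!parameter %in% names(table))
    stop("parameter '", parameter, "' not in cohort table")
  if (!"group" %in% names(table))
    stop("cohort table needs a 'group' column")
  invisible(TRUE)
}

#' Kruskal-Wallis test of a parameter across groups
#'
#' Rank-based omnibus test with tie correction; p from the chi-square
#' approximation with `groups - 1` degrees of freedom.
#'
#' @param table Cohort data frame with a `group` column.
#' @param parameter Column name to test.
#' @return List with `H` (test statistic), `p`, and `df`.
#' @export
kruskal_wallis <- function(table, parameter) {
  .check_cohort(table, parameter)
  g <- factor(table$group)
  if (nlevels(g) < 2) stop("kruskal_wallis: need >= 2 groups")
  if (any(tabulate(g) < 2)) stop("kruskal_wallis: each group needs n >= 2")
  x <- table[[parameter]]
  if (stats::sd(x) == 0) {
    # fully tied: every rank is the mid-rank, H is 0 by convention
    return(list(H = 0, p = 1, df = nlevels(g) - 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Mann-Whitney comparisons of each patient group against normals
#'
#' Two-sided Mann-Whitney U of every non-reference group versus the
#' reference (normal) group, Bonferroni-corrected over the family of
#' comparisons performed for this parameter (by default the number of
#' patient groups). Significance is declared at corrected p < 0.05.
#'
#' @param table Cohort data frame.
#' @param parameter Column name to test.
#' @param reference Name of the reference group (default `"norm"`).
#' @param family Bonferroni family size; defaults to the number of
#'   comparisons performed (set to `7 * that` for a global
#'   all-parameters family).
#' @return Data frame with one row per patient group: `group, U, p_raw,
#'   p_bonferroni, significant`.
#' @export
pairwise_vs_normal <- function(table, parameter, reference = "norm",
                               family = NULL) {
  .check_cohort(table, parameter)
  if (!reference %in% table$group)
    stop("pairwise_vs_normal: reference group '", reference, "' missing")
  others <- setdiff(unique(table$group), reference)
  if (is.null(family)) family <- length(others)
  ref_x <- table[[parameter]][table$group == reference]
  res <- lapply(others, function(g) {
    x <- table[[parameter]][table$group == g]
    wt <- suppressWarnings(
      stats::wilcox.test(x, ref_x, alternative = "two.sided",
                         exact = NULL, correct = TRUE))
    p_b <- min(1, family * wt$p.value)
    data.frame(group = g, U = unname(wt$statistic), p_raw = wt$p.value,
               p_bonferroni = p_b, significant = p_b < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Spearman correlation of a parameter with a covariate
#'
#' Rank correlation with average-rank ties; p from the t approximation.
#'
#' @param table Cohort data frame.
#' @param parameter Column name.
#' @param covariate Covariate column (default `rnfl_um`).
#' @return List with `R` (rho) and `p`.
#' @export
spearman_correlation <- function(table, parameter, covariate = "rnfl_um") {
  .check_cohort(table, parameter)
  x <- table[[parameter]]; y <- table[[covariate]]
  keep <- stats::complete.cases(x, y)
  if (sum(keep) < 3) stop("spearman_correlation: need >= 3 complete pairs")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    stop("spearman_correlation: constant column; rank correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x[keep], y[keep], method = "spearman", exact = FALSE))
  list(R = unname(ct$estimate), p = ct$p.value)
}

#' OLS regression of a parameter on a covariate
#'
#' Ordinary least squares; the slope is additionally reported per 10 units
#' of the covariate (the scale on which RNFL loss is usually quoted).
#'
#' @inheritParams spearman_correlation
#' @return List with `slope`, `intercept`, `slope_per_10`.
#' @export
regression_slope <- function(table, parameter, covariate = "rnfl_um") {
  .check_cohort(table, parameter)
  x <- table[[covariate]]; y <- table[[parameter]]
  keep <- stats::complete.cases(x, y)
  if (sum(keep) < 3) stop("regression_slope: need >= 3 pairs")
  if (stats::sd(x[keep]) == 0)
    stop("regression_slope: constant covariate")
  fit <- stats::lm(y[keep] ~ x[keep])
  co <- unname(stats::coef(fit))
  list(slope = co[2], intercept = co[1], slope_per_10 = 10 * co[2])
}

#' Coefficient of variation from two repeated measurements
#'
#' Test-retest reproducibility: CV = sqrt(within-subject mean square from
#' a one-way repeated-measures ANOVA) / grand mean. Requires exactly two
#' repeats per subject (the design used for the reproducibility
#' assessment).
#'
#' @param table Data frame with columns `subject_id`, `repeat_id`, and the
#'   parameter.
#' @param parameter Column name.
#' @return The coefficient of variation (dimensionless).
#' @export
cv_repeated <- function(table, parameter) {
  if (!all(c("subject_id", "repeat_id") %in% names(table)))
    stop("cv_repeated: table needs subject_id and repeat_id columns")
  if (!parameter %in% names(table))
    stop("parameter '", parameter, "' not in table")
  counts <- table(table$subject_id)
  if (length(counts) < 2) stop("cv_repeated: need >= 2 subjects")
  if (any(counts != 2))
    stop("cv_repeated: every subject must have exactly 2 repeats; got ",
         paste(sprintf("%s:%d", names(counts)[counts != 2],
                       counts[counts != 2]), collapse = ", "))
  y <- table[[parameter]]
  subj <- factor(table$subject_id)
  fit <- stats::aov(y ~ subj)
  ms_within <- sum(stats::residuals(fit)^2) / fit$df.residual
  sqrt(ms_within) / mean(y)
}

#' Per-group summary of a cohort table
#'
#' Mean +- SD of every pulse parameter by group, in the layout of a
#' group-statistics table, plus the omnibus Kruskal-Wallis p per
#' parameter.
#'
#' @param table Cohort data frame.
#' @param parameters Parameter columns to summarize (default: the seven
#'   pulse parameters present).
#' @return List with `summary` (data frame group x parameter "mean +- sd")
#'   and `kruskal` (named vector of p-values).
#' @export
cohort_summary <- function(table,
                           parameters = intersect(
                             c("peak_amplitude", "steepness", "ttp_s",
                               "ttp_pct", "fwhm_s", "fwhm_pct",
                               "duration_s"), names(table))) {
  .check_cohort(table, parameters[1])
  groups <- unique(table$group)
  summ <- sapply(parameters, function(p) {
    sapply(groups, function(g) {
      x <- table[[p]][table$group == g]
      sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
    })
  })
  summ <- as.data.frame(summ, stringsAsFactors = FALSE)
  summ <- cbind(group = groups, n = as.integer(table(factor(table$group, groups))),
                summ, stringsAsFactors = FALSE)
  kw <- vapply(parameters, function(p) kruskal_wallis(table, p)$p, numeric(1))
  list(summary = summ, kruskal = kw)
}
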