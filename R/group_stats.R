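# Group-comparison statistics applied to per-cell measurements: one-way
# ANOVA with Tukey HSD for stage/condition comparisons of continuous
# statistics, Fisher's exact test plus Pearson's chi-squared (no continuity
# correction) for categorical score tables, a two-sample t-test on arcsine
# square-root transformed proportions for induction rates, and SEM
# summaries.  These wrap R's reference implementations; tests validate them
# against hand-computed sums of squares and hypergeometric enumeration.

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param values numeric response per cell.
#' @param group group label per cell (>= 2 groups, each n >= 2).
#' @return List with `F`, `p`, `df_between`, `df_within`, and `tukey`
#'   (data.frame of pairwise differences with Tukey-adjusted p-values).
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  n_per <- table(group)
  if (any(n_per < 2)) stop("each group needs n >= 2")
  if (all(vapply(split(values, group), function(v) stats::var(v) == 0,
                 logical(1))))
    stop("degenerate: zero within-group variance in every group")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = tab[["F value"]][1],
       p = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2],
       tukey = data.frame(pair = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Fisher's exact test and Pearson's chi-squared on a contingency table
#'
#' Two-sided Fisher exact p (summing hypergeometric probabilities of all
#' tables at most as probable as the observed one; 2x2 tables only) and the
#' Pearson chi-squared statistic without Yates continuity correction (any
#' r x c). Tables with a zero margin are flagged degenerate and return NA
#' p-values rather than erroring.
#'
#' @param counts integer matrix of non-negative counts.
#' @return List with `fisher_p` (NA unless 2x2), `chi2`, `chi2_df`,
#'   `chi2_p`, `degenerate`.
#' @export
fisher_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate)
    return(list(fisher_p = NA_real_, chi2 = NA_real_, chi2_df = NA_real_,
                chi2_p = NA_real_, degenerate = TRUE))
  fisher_p <- if (all(dim(counts) == c(2, 2)))
    stats::fisher.test(counts)$p.value else NA_real_
  cs <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(fisher_p = fisher_p,
       chi2 = unname(cs$statistic), chi2_df = unname(cs$parameter),
       chi2_p = cs$p.value, degenerate = FALSE)
}

#' Two-sample t-test on arcsine square-root transformed proportions
#'
#' The variance-stabilizing transform `x -> asin(sqrt(x))` is applied to the
#' per-trial proportions of each arm, followed by a Student (pooled
#' variance) two-sample t-test.
#'
#' @param props_a,props_b per-trial proportions in `[0, 1]`, each of
#'   length 2 or more.
#' @return List with `t`, `df`, `p`, and the transformed arm means.
#' @export
arcsine_prop_test <- function(props_a, props_b) {
  check <- function(p, nm) {
    if (length(p) < 2) stop(sprintf("%s needs at least 2 trials", nm))
    if (any(p < 0 | p > 1)) stop(sprintf("%s must lie in [0, 1]", nm))
  }
  check(props_a, "props_a"); check(props_b, "props_b")
  ta <- asin(sqrt(props_a)); tb <- asin(sqrt(props_b))
  ht <- stats::t.test(ta, tb, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(ta), mean_b = mean(tb))
}

#' Per-group mean, SEM and n
#'
#' SEM is `sd / sqrt(n)`; a singleton group reports SEM 0 with `n = 1` so
#' downstream plotting does not drop the group silently.
#'
#' @param values numeric vector.
#' @param group group label per value.
#' @return data.frame with `group`, `mean`, `sem`, `n`.
#' @export
summarize_groups <- function(values, group) {
  sp <- split(values, factor(group))
  out <- data.frame(
    group = names(sp),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v)), numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
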