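#' Summarize per-animal records into a group-level cohort table
#'
#' For each group and each numeric field, reports the per-field `n` (missing
#' assay values are excluded field-wise), mean, and standard error
#' (`SD/sqrt(n)`; 0 by convention for `n = 1`, flagged `low_n`).
#'
#' @param records data.frame of per-animal rows (e.g. [aggregate_record]
#'   rows bound together) with a `group_label` column.
#' @param fields fields to summarize (default: all numeric columns).
#' @return data.frame of class `cohort_table` with columns `field`,
#'   `group_label`, `n`, `mean`, `se`, `low_n`.
#' @export
summarize_cohort <- function(records, fields = NULL) {
  if (!nrow(records)) stopf("no records to summarize")
  if (is.null(fields))
    fields <- names(records)[vapply(records, is.numeric, logical(1L))]
  groups <- unique(records$group_label)
  out <- list()
  for (g in groups) {
    sub <- records[records$group_label == g, , drop = FALSE]
    if (!nrow(sub)) stopf("empty group: %s", g)
    for (f in fields) {
      x <- sub[[f]]
      x <- x[is.finite(x)]
      n <- length(x)
      out[[length(out) + 1L]] <- data.frame(
        field = f, group_label = g, n = n,
        mean = if (n) mean(x) else NA_real_,
        se = if (n > 1L) stats::sd(x) / sqrt(n) else if (n == 1L) 0 else NA_real_,
        low_n = n <= 1L)
    }
  }
  structure(do.call(rbind, out), class = c("cohort_table", "data.frame"))
}

# Monte-Carlo sample of the null max-|t| statistic for Dunnett many-to-one
# comparisons with group sizes n (control first) and error df. Draws group
# means and a pooled scale from the fitted null, vectorized over reps.
dunnett_null_maxt <- function(n, df, mc_reps, seed = NULL) {
  with_seed(seed, {
    k <- length(n) - 1L
    z0 <- stats::rnorm(mc_reps, 0, sqrt(1 / n[1L]))
    s <- sqrt(stats::rchisq(mc_reps, df) / df)
    tmat <- vapply(seq_len(k), function(i) {
      zi <- stats::rnorm(mc_reps, 0, sqrt(1 / n[i + 1L]))
      (zi - z0) / (s * sqrt(1 / n[i + 1L] + 1 / n[1L]))
    }, numeric(mc_reps))
    apply(abs(tmat), 1L, max)
  })
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Classical one-way ANOVA F test plus Dunnett's comparisons of every
#' treated group against the control. Adjusted two-sided p-values are
#' obtained from the null distribution of the maximum |t| statistic,
#' estimated by seeded Monte Carlo from the fitted null (multivariate t
#' implied by the shared control and pooled variance), which is exact in
#' distribution at arbitrary unbalanced group sizes.
#'
#' @param values named list of numeric vectors, one per group, or a
#'   data.frame with columns `value` and `group_label`.
#' @param control name of the control group (default: first group).
#' @param mc_reps Monte-Carlo draws for the max-|t| null (default 4000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @return list of class `test_result`: `statistic` (F), `p_value` (ANOVA),
#'   `method`, `comparisons` (data.frame: group, estimate, t, p_unadjusted,
#'   p_adjusted), `seed`.
#' @export
anova_dunnett <- function(values, control = NULL, mc_reps = 4000, seed = NULL) {
  if (is.data.frame(values))
    values <- split(values$value, values$group_label)
  if (length(values) < 2L) stopf("need >= 2 groups")
  if (any(vapply(values, length, integer(1L)) < 2L))
    stopf("every group needs n >= 2")
  if (is.null(control)) control <- names(values)[1L]
  if (!control %in% names(values)) stopf("unknown control group: %s", control)
  values <- c(values[control], values[setdiff(names(values), control)])
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  y <- unlist(values, use.names = FALSE)
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1L]]
  ms_err <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  if (ms_err <= 0) stopf("zero within-group variance everywhere")
  n <- lengths(values)
  means <- vapply(values, mean, numeric(1L))
  est <- means[-1L] - means[1L]
  tstat <- est / sqrt(ms_err * (1 / n[-1L] + 1 / n[1L]))
  p_un <- 2 * stats::pt(abs(tstat), df_err, lower.tail = FALSE)
  maxt <- dunnett_null_maxt(n, df_err, mc_reps, seed = seed)
  p_adj <- vapply(abs(tstat), function(t0)
    (1 + sum(maxt >= t0)) / (mc_reps + 1), numeric(1L))
  p_adj <- pmax(p_adj, p_un)
  structure(list(statistic = an["g", "F value"],
                 p_value = an["g", "Pr(>F)"],
                 method = sprintf("one-way ANOVA + Dunnett vs '%s' (Monte-Carlo, %d reps)",
                                  control, mc_reps),
                 comparisons = data.frame(group = names(values)[-1L],
                                          estimate = as.numeric(est),
                                          t = as.numeric(tstat),
                                          p_unadjusted = as.numeric(p_un),
                                          p_adjusted = as.numeric(p_adj)),
                 seed = seed),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, p = %.4g\n", x$method,
              x$statistic, x$p_value))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation with permutation p-value
#'
#' Spearman's r_s via midranks (ties averaged) followed by product-moment
#' correlation; the two-sided p-value is obtained by permuting `y` with the
#' add-one estimator `p = (1 + #{|r_perm| >= |r_s|}) / (n_perm + 1)`, which
#' is valid (never anti-conservative) at any `n_perm`.
#'
#' @param x,y paired samples (>= 4 pairs, neither constant).
#' @param n_perm number of permutations (default 10000, >= 100).
#' @param seed integer seed for the permutations.
#' @return list of class `test_result` with `statistic` (r_s), `p_value`,
#'   `method`, `seed`.
#' @export
spearman_permutation <- function(x, y, n_perm = 10000, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need >= 4 complete pairs")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stopf("r_s undefined for constant x or y")
  r_obs <- stats::cor(rx, ry)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stats::cor(rx, sample(ry)), numeric(1L)))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  structure(list(statistic = r_obs, p_value = p,
                 method = sprintf("Spearman rank correlation, permutation p (%d perms)",
                                  n_perm),
                 comparisons = NULL, seed = seed),
            class = "test_result")
}

#' Ordinary least-squares correlation
#'
#' Simple linear correlation: OLS slope/intercept of `y` on `x`, Pearson r
#' and its square.
#'
#' @param x,y paired samples (>= 3 pairs, `x` not constant).
#' @return list with `r`, `r2`, `slope`, `intercept`, `n`.
#' @export
linear_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 complete pairs")
  if (stats::sd(x) == 0) stopf("x is constant; correlation undefined")
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  list(r = r, r2 = r^2, slope = slope,
       intercept = mean(y) - slope * mean(x), n = length(x))
}

#' Correlation between two fields at the group-mean level
#'
#' Applies [linear_correlation] to the per-group means of two fields of a
#' cohort table — e.g. group-mean collagen content (OHP) against group-mean
#' RV chamber compliance, the fibrosis-compliance relationship.
#'
#' @param cohort a `cohort_table` from [summarize_cohort].
#' @param xfield,yfield field names to correlate.
#' @return as [linear_correlation], plus the `groups` used.
#' @export
group_mean_correlation <- function(cohort, xfield, yfield) {
  cx <- cohort[cohort$field == xfield, ]
  cy <- cohort[cohort$field == yfield, ]
  groups <- intersect(cx$group_label[is.finite(cx$mean)],
                      cy$group_label[is.finite(cy$mean)])
  if (length(groups) < 3L) stopf("need >= 3 groups with both fields")
  res <- linear_correlation(cx$mean[match(groups, cx$group_label)],
                            cy$mean[match(groups, cy$group_label)])
  res$groups <- groups
  res
}
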