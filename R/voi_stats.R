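#' Cohen's d with confidence interval from group summaries
#'
#' Standardized mean difference using the pooled SD, with the sign
#' convention that positive values indicate larger volumes in the
#' comparison group (males): `d = (mean_m - mean_f) / sd_pooled`. The 95%
#' confidence interval uses the large-sample standard error
#' `sqrt((n1+n2)/(n1*n2) + d^2/(2*(n1+n2)))` with a normal quantile;
#' a noncentral-t interval is available with `ci = "noncentral"`.
#'
#' @param mean_m,mean_f Group means (comparison group M first).
#' @param sd_m,sd_f Group standard deviations (> 0).
#' @param n_m,n_f Group sizes.
#' @param conf Confidence level, default 0.95.
#' @param ci `"normal"` (large-sample, default) or `"noncentral"`
#'   (noncentral-t inversion).
#' @return List with `d`, `se`, `ci_low`, `ci_high`, `direction`
#'   (`"M>F"`, `"F>M"` or `"none"`, judged by whether the interval
#'   excludes zero).
#' @examples
#' cohens_d(1546.191, 1545.111, 75.397, 77.372, 74, 74)$d  # ~0.01
#' @export
cohens_d <- function(mean_m, mean_f, sd_m, sd_f, n_m, n_f,
                     conf = 0.95, ci = c("normal", "noncentral")) {
  ci <- match.arg(ci)
  sp <- sqrt(((n_m - 1) * sd_m^2 + (n_f - 1) * sd_f^2) / (n_m + n_f - 2))
  if (sp == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean_m - mean_f) / sp
  n <- n_m + n_f
  se <- sqrt(n / (n_m * n_f) + d^2 / (2 * n))
  if (ci == "normal") {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    lo <- d - z * se; hi <- d + z * se
  } else {
    mult <- sqrt(1 / n_m + 1 / n_f)
    t_obs <- d / mult
    df <- n - 2
    alpha <- (1 - conf) / 2
    ncp_bound <- function(prob) {
      f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - prob
      stats::uniroot(f, lower = t_obs - 10 * (1 + abs(t_obs)),
                     upper = t_obs + 10 * (1 + abs(t_obs)),
                     extendInt = "yes")$root
    }
    lo <- ncp_bound(1 - alpha) * mult
    hi <- ncp_bound(alpha) * mult
  }
  direction <- if (lo > 0) "M>F" else if (hi < 0) "F>M" else "none"
  list(d = d, se = se, ci_low = lo, ci_high = hi, direction = direction)
}

#' Cohen's d from a pooled-variance t statistic
#'
#' Algebraic identity for the two-sample pooled t test:
#' `d = t * sqrt(1/n1 + 1/n2)`. Exactly consistent with [cohens_d()] on
#' the same data.
#'
#' @param t Pooled-variance t statistic (M minus F orientation).
#' @param n1,n2 Group sizes.
#' @return Cohen's d.
#' @examples
#' d_from_t(15.05, 185, 171)  # ~1.596
#' @export
d_from_t <- function(t, n1, n2) t * sqrt(1 / n1 + 1 / n2)

#' Pooled two-sample t test from group summaries
#'
#' Student's t test for independent groups computed from means, SDs and
#' sizes, with Cohen's d and its confidence interval. Lets printed summary
#' tables be re-analyzed without subject-level data.
#'
#' @inheritParams cohens_d
#' @param alpha Significance threshold for the direction call.
#' @return List with `t`, `df`, `p` (two-sided), `significant`, and the
#'   `effect` list from [cohens_d()] with direction consistent with the
#'   test at `alpha`.
#' @examples
#' ttest_from_summary(1546.191, 1545.111, 75.397, 77.372, 74, 74)$t # 0.086
#' @export
ttest_from_summary <- function(mean_m, mean_f, sd_m, sd_f, n_m, n_f,
                               alpha = 0.05) {
  eff <- cohens_d(mean_m, mean_f, sd_m, sd_f, n_m, n_f)
  t <- eff$d / sqrt(1 / n_m + 1 / n_f)
  df <- n_m + n_f - 2
  p <- 2 * stats::pt(-abs(t), df)
  sig <- p < alpha
  eff$direction <- if (!sig) "none" else if (eff$d > 0) "M>F" else "F>M"
  list(t = t, df = df, p = p, significant = sig, effect = eff)
}

#' Per-VOI Student t tests on an adjusted (or raw) dataset
#'
#' Runs one pooled-variance two-sided t test per region, comparing males
#' versus females, and summarizes each with Cohen's d and its 95% CI.
#' Positive d means larger male volumes.
#'
#' @param dataset An `adjusted_dataset` or `cohort_table`.
#' @param alpha Significance threshold (default 0.05); p values below
#'   `marginal_alpha` but above `alpha` are flagged as marginal, mirroring
#'   the looser reporting threshold conventionally used in half-size
#'   subsamples.
#' @param marginal_alpha Marginal threshold (default 0.1).
#' @return Data frame of class `voi_stats` with one row per VOI: group
#'   means/SDs, `t`, `df`, `p`, `d`, `ci_low`, `ci_high`, `direction`,
#'   `significant`, `marginal`. The adjustment method is kept in attribute
#'   `method`.
#' @export
ttest_by_voi <- function(dataset, alpha = 0.05, marginal_alpha = 0.1) {
  check_two_groups(dataset)
  y <- voi_matrix(dataset)
  m_idx <- dataset$group == "M"
  n_m <- sum(m_idx); n_f <- sum(!m_idx)
  mean_m <- colMeans(y[m_idx, , drop = FALSE])
  mean_f <- colMeans(y[!m_idx, , drop = FALSE])
  var_m <- apply(y[m_idx, , drop = FALSE], 2, stats::var)
  var_f <- apply(y[!m_idx, , drop = FALSE], 2, stats::var)
  sp <- sqrt(((n_m - 1) * var_m + (n_f - 1) * var_f) / (n_m + n_f - 2))
  d <- (mean_m - mean_f) / sp
  t <- d / sqrt(1 / n_m + 1 / n_f)
  df <- n_m + n_f - 2
  p <- 2 * stats::pt(-abs(t), df)
  n <- n_m + n_f
  se_d <- sqrt(n / (n_m * n_f) + d^2 / (2 * n))
  z <- stats::qnorm(0.975)
  sig <- p < alpha
  out <- data.frame(voi = voi_names(dataset),
                    mean_m = mean_m, sd_m = sqrt(var_m),
                    mean_f = mean_f, sd_f = sqrt(var_f),
                    n_m = n_m, n_f = n_f,
                    t = t, df = df, p = p,
                    d = d, ci_low = d - z * se_d, ci_high = d + z * se_d,
                    direction = ifelse(!sig, "none",
                                       ifelse(d > 0, "M>F", "F>M")),
                    significant = sig,
                    marginal = !sig & p < marginal_alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, method = adjustment_method(dataset), alpha = alpha,
            class = c("voi_stats", "data.frame"))
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group means
#' (mean-centered variant).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (2 or more levels).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  z <- abs(values - stats::ave(values, groups))
  k <- nlevels(groups); n <- length(values)
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ss_between <- sum(ng * (zg - zbar)^2)
  ss_within <- sum((z - stats::ave(z, groups))^2)
  Fstat <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(F = Fstat, df1 = k - 1, df2 = n - k,
       p = stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE))
}

#' Per-VOI linear regressions of (adjusted) volumes on TIV
#'
#' The central validity diagnostic for a TIV-adjustment method: properly
#' adjusted volumes should show no remaining linear relationship with TIV,
#' so every slope should be indistinguishable from zero.
#'
#' @param dataset An `adjusted_dataset` or `cohort_table`.
#' @return Data frame of class `tiv_regression` with one row per VOI:
#'   `slope`, `intercept`, `r2`, `slope_p` and `pct_variance`
#'   (`100 * r2`).
#' @export
tiv_regression <- function(dataset) {
  x <- dataset$tiv
  if (stats::sd(x) == 0)
    stop("degenerate design: TIV is constant across the sample",
         call. = FALSE)
  y <- voi_matrix(dataset)
  n <- length(x)
  f <- ols_columns(x, y)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  fitted <- outer(x, f$slope) + matrix(f$intercept, n, ncol(y), byrow = TRUE)
  rss <- colSums((y - fitted)^2)
  tss <- colSums(scale(y, scale = FALSE)^2)
  r2 <- 1 - rss / tss
  se_slope <- sqrt(rss / (n - 2) / sxx)
  tval <- f$slope / se_slope
  p <- 2 * stats::pt(-abs(tval), n - 2)
  structure(data.frame(voi = voi_names(dataset),
                       slope = f$slope, intercept = f$intercept,
                       r2 = r2, slope_p = p, pct_variance = 100 * r2,
                       row.names = NULL, stringsAsFactors = FALSE),
            method = adjustment_method(dataset),
            class = c("tiv_regression", "data.frame"))
}

#' Rank correlation of TIV-VOI slopes with difference outcomes
#'
#' Spearman correlations of the per-VOI TIV-VOI regression slopes with the
#' significance levels (p) and effect sizes (d) of the group differences.
#' On raw data, steeper TIV scaling predicts larger and more significant
#' "sex" differences; after a valid adjustment both correlations should
#' vanish.
#'
#' @param reg A `tiv_regression` table.
#' @param stats A `voi_stats` table over the same VOIs.
#' @return List with `rho_slope_p`, `p_slope_p`, `rho_slope_d`,
#'   `p_slope_d`.
#' @export
slope_outcome_correlation <- function(reg, stats) {
  if (!identical(reg$voi, stats$voi))
    stop("regression and stats tables cover different VOI sets",
         call. = FALSE)
  ct_p <- suppressWarnings(
    stats::cor.test(reg$slope, stats$p, method = "spearman"))
  ct_d <- suppressWarnings(
    stats::cor.test(reg$slope, stats$d, method = "spearman"))
  list(rho_slope_p = unname(ct_p$estimate), p_slope_p = ct_p$p.value,
       rho_slope_d = unname(ct_d$estimate), p_slope_d = ct_d$p.value)
}

#' Association between TIV-slope significance and difference significance
#'
#' Cross-tabulates the VOIs by whether their TIV-VOI slope is significant
#' and whether their group difference is significant, and tests the
#' association with a chi-squared test (no continuity correction).
#'
#' @param reg A `tiv_regression` table.
#' @param stats A `voi_stats` table over the same VOIs.
#' @param alpha Significance threshold applied to both criteria.
#' @return List with `chi2`, `df`, `p`, `table` (2x2 contingency) and
#'   `testable` (`FALSE` when a margin is degenerate, in which case the
#'   test statistics are `NA`).
#' @export
slope_frequency_test <- function(reg, stats, alpha = 0.05) {
  if (!identical(reg$voi, stats$voi))
    stop("regression and stats tables cover different VOI sets",
         call. = FALSE)
  slope_sig <- factor(reg$slope_p < alpha, levels = c(TRUE, FALSE))
  diff_sig <- factor(stats$p < alpha, levels = c(TRUE, FALSE))
  tab <- table(slope_significant = slope_sig, diff_significant = diff_sig)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_, table = tab,
                testable = FALSE))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(chi$statistic), df = unname(chi$parameter),
       p = chi$p.value, table = tab, testable = TRUE)
}

#' Minimum detectable effect size (sensitivity power analysis)
#'
#' Smallest Cohen's d a two-sided two-sample pooled t test can detect with
#' the requested power, using the noncentral-t power function with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))`.
#'
#' @param n1,n2 Group sizes.
#' @param power Target power (default 0.8).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Minimum detectable d.
#' @examples
#' min_detectable_d(185, 171)  # ~0.30
#' @export
min_detectable_d <- function(n1, n2, power = 0.8, alpha = 0.05) {
  df <- n1 + n2 - 2
  crit <- stats::qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  }
  stats::uniroot(function(d) pow(d) - power, c(1e-6, 10),
                 tol = 1e-10)$root
}
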