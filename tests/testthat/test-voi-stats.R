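test_that("printed TIV-matched summaries reproduce the benchmark t and d", {
  tt <- ttest_from_summary(1546.191, 1545.111, 75.397, 77.372, 74, 74)
  expect_equal(round(tt$t, 3), 0.086)
  expect_equal(tt$df, 146)
  expect_equal(round(tt$p, 3), 0.932)
  expect_equal(round(tt$effect$d, 2), 0.01)
  expect_equal(tt$effect$direction, "none")
})

test_that("education summaries give a negligible standardized difference", {
  eff <- cohens_d(14.61, 14.56, 2.21, 2.10, 185, 171)
  expect_equal(round(eff$d, 2), 0.02)
  expect_equal(round(eff$ci_low, 2), -0.18)
  expect_equal(round(eff$ci_high, 2), 0.23)
})

test_that("d from t recovers the headline TIV effect size and matches cohens_d exactly", {
  # t is printed to 2 decimals, so d is recovered to ~3 decimals
  expect_equal(d_from_t(15.05, 185, 171), 1.596, tolerance = 5e-4)
  expect_equal(d_from_t(0, 50, 60), 0)
  set.seed(19)
  for (rep in 1:5) {
    x <- rnorm(14, 10, 2); y <- rnorm(11, 11, 2)
    sp <- sqrt((13 * var(x) + 10 * var(y)) / 23)
    t_stat <- (mean(x) - mean(y)) / (sp * sqrt(1 / 14 + 1 / 11))
    eff <- cohens_d(mean(x), mean(y), sd(x), sd(y), 14, 11)
    expect_equal(d_from_t(t_stat, 14, 11), eff$d, tolerance = 1e-12)
  }
})

test_that("the large-sample d interval matches the textbook SE formula", {
  eff <- cohens_d(15.05 * sqrt(1 / 185 + 1 / 171) * 76 + 0, 0, 76, 76,
                  185, 171)
  se <- sqrt(356 / (185 * 171) + eff$d^2 / (2 * 356))
  expect_equal(eff$ci_low, eff$d - qnorm(0.975) * se)
  expect_equal(eff$ci_high, eff$d + qnorm(0.975) * se)
  # noncentral-t variant brackets the same d and nearly agrees at this n
  nct <- cohens_d(eff$d * 76, 0, 76, 76, 185, 171, ci = "noncentral")
  expect_lt(abs(nct$ci_low - eff$ci_low), 0.02)
  expect_lt(abs(nct$ci_high - eff$ci_high), 0.02)
  expect_error(cohens_d(1, 0, 0, 0, 5, 5), "pooled")
})

test_that("per-VOI t tests agree with t.test(var.equal = TRUE) and code direction", {
  co <- toy_cohort(6, 7, p = 4, seed = 23)
  st <- ttest_by_voi(as_adjusted(co, "raw"))
  for (j in seq_along(st$voi)) {
    y <- co[[st$voi[j]]]
    ref <- t.test(y[co$group == "M"], y[co$group == "F"], var.equal = TRUE)
    expect_equal(st$t[j], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-12)
    expect_equal(st$df[j], unname(ref$parameter))
  }
  expect_true(all(st$direction[st$p >= 0.05] == "none"))
  expect_true(all(st$direction[st$p < 0.05 & st$d > 0] == "M>F"))
})

test_that("duplicating one group across labels yields t = 0, d = 0, no direction", {
  set.seed(29)
  base <- data.frame(tiv = rnorm(5, 1500, 60),
                     Precentral_L = runif(5, 2, 3),
                     Precentral_R = runif(5, 2, 3))
  d <- cbind(subject_id = sprintf("c%02d", 1:10),
             group = rep(c("F", "M"), each = 5),
             rbind(base, base))
  st <- ttest_by_voi(as_adjusted(cohort_table(d), "raw"))
  expect_equal(st$t, rep(0, 2))
  expect_equal(st$d, rep(0, 2))
  expect_equal(st$direction, rep("none", 2))
})

test_that("Levene's test matches car's mean-centered implementation", {
  set.seed(37)
  x <- c(rnorm(12, 5, 1), rnorm(15, 5, 2.5))
  g <- rep(c("a", "b"), c(12, 15))
  ours <- levene_test(x, g)
  ref <- car::leveneTest(x ~ factor(g), center = mean)
  expect_equal(ours$F, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
  # identical groups and pure location shifts give F = 0
  expect_equal(levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$F, 0)
  expect_equal(levene_test(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))$F, 0)
})

test_that("TIV-VOI regressions match lm slope, p value and R^2", {
  co <- toy_cohort(7, 7, p = 4, seed = 41)
  reg <- tiv_regression(as_adjusted(co, "raw"))
  for (j in seq_along(reg$voi)) {
    ref <- summary(lm(co[[reg$voi[j]]] ~ co$tiv))
    expect_equal(reg$slope[j], ref$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(reg$intercept[j], ref$coefficients[1, 1], tolerance = 1e-10)
    expect_equal(reg$slope_p[j], ref$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(reg$r2[j], ref$r.squared, tolerance = 1e-10)
    expect_equal(reg$pct_variance[j], 100 * ref$r.squared)
  }
})

test_that("noiseless proportional volumes give R^2 = 1 and residual adjustment kills slopes", {
  atlas <- aal116_atlas()
  vp <- data.frame(name = atlas$name[1:3], c = c(0.002, 0.004, 0.001),
                   b = 1, sigma = 0, delta = 0)
  spec <- generator_spec(c(F = 8L, M = 8L), c(F = 1450, M = 1570),
                         c(F = 70, M = 70), vp, seed = 5)
  co <- generate_cohort(spec)$cohort
  expect_equal(tiv_regression(as_adjusted(co, "raw"))$r2, rep(1, 3))
  reg_adj <- tiv_regression(adjust_residuals(co))
  expect_true(all(abs(reg_adj$slope) < 1e-10))
})

test_that("slope-outcome rank correlations behave at the extremes and under the confound", {
  reg <- data.frame(voi = paste0("v", 1:8), slope = 1:8,
                    r2 = runif(8), slope_p = runif(8))
  st <- data.frame(voi = paste0("v", 1:8), p = rev(1:8) / 10, d = 1:8 / 10)
  out <- slope_outcome_correlation(reg, st)
  expect_equal(out$rho_slope_p, -1)
  expect_equal(out$rho_slope_d, 1)
  expect_error(slope_outcome_correlation(reg, st[c(2:8, 1), ]), "VOI")
  # raw synthetic data reproduce the mechanism: steeper slope, smaller p
  sim <- generate_cohort(study_spec(seed = 47))
  raw <- as_adjusted(sim$cohort, "raw")
  mech <- slope_outcome_correlation(tiv_regression(raw), ttest_by_voi(raw))
  expect_lt(mech$rho_slope_p, 0)
  expect_gt(mech$rho_slope_d, 0)
})

test_that("the slope/difference frequency test is an uncorrected chi-squared", {
  # contingency layout: slope significant x difference significant
  reg <- data.frame(voi = paste0("v", 1:116),
                    slope_p = rep(c(0.01, 0.5), c(52, 64)))
  st <- data.frame(voi = paste0("v", 1:116),
                   p = c(rep(0.01, 41), rep(0.5, 11),
                         rep(0.01, 30), rep(0.5, 34)),
                   d = 1)
  out <- slope_frequency_test(reg, st)
  expect_true(out$testable)
  # independent hand computation from the 2x2 margins
  tab <- matrix(c(41, 11, 30, 34), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / 116
  expect_equal(out$chi2, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(round(out$chi2, 2), 12.35)
  expect_equal(round(out$p, 4), 4e-04)
  # degenerate margins are flagged untestable, not an error
  st$p <- 0.01
  deg <- slope_frequency_test(reg, st)
  expect_false(deg$testable)
  expect_true(is.na(deg$chi2))
})

test_that("sensitivity power analysis inverts the noncentral-t power function", {
  d_min <- min_detectable_d(185, 171, power = 0.8, alpha = 0.05)
  expect_gte(d_min, 0.29)
  expect_lt(d_min, 0.31)
  # at the solution the achieved power is 0.8
  ncp <- d_min * sqrt(185 * 171 / 356)
  crit <- qt(0.975, 354)
  pow <- 1 - pt(crit, 354, ncp) + pt(-crit, 354, ncp)
  expect_equal(pow, 0.8, tolerance = 1e-8)
  # equal-n case agrees with power.t.test's delta solver
  ref <- power.t.test(n = 100, power = 0.8, sig.level = 0.05)
  expect_equal(min_detectable_d(100, 100), ref$delta, tolerance = 1e-4)
})
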