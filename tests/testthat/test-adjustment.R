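test_that("proportion adjustment is a plain TIV ratio", {
  co <- toy_cohort(4, 4, p = 3, seed = 2)
  adj <- adjust_proportion(co)
  expect_equal(adjustment_method(adj), "proportion")
  expect_equal(voi_matrix(adj), voi_matrix(co) / co$tiv)
  # hand instance: 7.5 ml over 1500 ml
  d <- data.frame(subject_id = c("h1", "h2"), group = c("F", "M"),
                  tiv = c(1500, 1600), Hippocampus_L = c(7.5, 8))
  expect_equal(adjust_proportion(cohort_table(d))$Hippocampus_L[1], 0.005)
  # scale invariance: doubling a subject's VOI and TIV leaves the ratio
  d2 <- d; d2$tiv[1] <- 3000; d2$Hippocampus_L[1] <- 15
  expect_equal(adjust_proportion(cohort_table(d2))$Hippocampus_L[1], 0.005)
})

test_that("a column equal to a multiple of TIV becomes constant after proportion adjustment", {
  co <- toy_cohort(5, 5, p = 2, seed = 3)
  co$Precentral_L <- 0.4 * co$tiv
  adj <- adjust_proportion(co)
  expect_equal(adj$Precentral_L, rep(0.4, 10))
})

test_that("PCP fitting matches lm on the log-log scale and is base-invariant", {
  co <- toy_cohort(6, 6, p = 4, seed = 5)
  fits <- fit_pcp(co)
  for (j in seq_along(fits$voi)) {
    ref <- lm(log(co[[fits$voi[j]]]) ~ log(co$tiv))
    expect_equal(fits$b[j], unname(coef(ref)[2]), tolerance = 1e-12)
    expect_equal(fits$intercept[j], unname(coef(ref)[1]), tolerance = 1e-12)
    ref10 <- lm(log10(co[[fits$voi[j]]]) ~ log10(co$tiv))
    expect_equal(fits$b[j], unname(coef(ref10)[2]), tolerance = 1e-12)
  }
  co$Precentral_L[1] <- 0
  expect_error(fit_pcp(co), "positive")
})

test_that("PCP recovers the generating exponent exactly on noiseless data", {
  atlas <- aal116_atlas()
  vp <- data.frame(name = atlas$name[1], c = 0.005, b = 0.863,
                   sigma = 0, delta = 0)
  spec <- generator_spec(c(F = 10L, M = 10L), c(F = 1450, M = 1570),
                         c(F = 70, M = 70), vp, seed = 3)
  co <- generate_cohort(spec)$cohort
  expect_equal(fit_pcp(co)$b, 0.863, tolerance = 1e-12)
  # adjusted values collapse to the scale constant
  adj <- adjust_pcp(co)
  expect_equal(unname(voi_matrix(adj)[, 1]), rep(0.005, 20),
               tolerance = 1e-9)
})

test_that("PCP limiting cases: b = 1 is the proportion method, b = 0 is raw", {
  co <- toy_cohort(4, 4, p = 2, seed = 7)
  fits1 <- data.frame(voi = voi_names(co), b = 1, intercept = 0)
  expect_equal(voi_matrix(adjust_pcp(co, fits1)),
               voi_matrix(adjust_proportion(co)))
  fits0 <- data.frame(voi = voi_names(co), b = 0, intercept = 0)
  expect_equal(voi_matrix(adjust_pcp(co, fits0)), voi_matrix(co))
  expect_error(adjust_pcp(co, fits0[1, ]), "missing PCP fit")
})

test_that("residuals adjustment matches the closed-form OLS hand computation", {
  # 5-subject instance small enough to verify by hand
  d <- data.frame(subject_id = paste0("r", 1:5),
                  group = c("F", "F", "M", "M", "M"),
                  tiv = c(1400, 1450, 1500, 1600, 1650),
                  Caudate_L = c(3.1, 3.3, 3.2, 3.8, 3.6))
  co <- cohort_table(d)
  b <- cov(d$tiv, d$Caudate_L) / var(d$tiv)
  adj <- adjust_residuals(co)
  expect_equal(adj$Caudate_L, d$Caudate_L - b * (d$tiv - mean(d$tiv)))
  expect_equal(fit_params(adj)$b[fit_params(adj)$voi == "Caudate_L"], b)
  expect_equal(unique(fit_params(adj)$tiv_mean), mean(d$tiv))
})

test_that("residual-adjusted volumes are exactly TIV-orthogonal and mean-preserving", {
  co <- toy_cohort(8, 8, p = 5, seed = 11)
  adj <- adjust_residuals(co)
  v_raw <- voi_matrix(co); v_adj <- voi_matrix(adj)
  for (j in seq_len(ncol(v_adj))) {
    expect_lt(abs(cov(v_adj[, j], co$tiv)), 1e-10)
    expect_equal(mean(v_adj[, j]), mean(v_raw[, j]))
  }
  # constant TIV is a degenerate design
  dd <- as.data.frame(co)[, 1:4]
  dd$tiv <- 1500
  expect_error(adjust_residuals(cohort_table(dd)), "degenerate")
})

test_that("covariate regression equals lm coefficient by coefficient", {
  co <- toy_cohort(6, 6, p = 3, seed = 13)
  fit <- fit_covariate_regression(co)
  sex <- as.numeric(co$group == "M")
  for (j in seq_along(fit$voi)) {
    y <- co[[fit$voi[j]]]
    ref <- summary(lm(y ~ co$tiv + sex))
    expect_equal(fit$b0[j], ref$coefficients[1, 1], tolerance = 1e-10)
    expect_equal(fit$b_tiv[j], ref$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(fit$b_sex[j], ref$coefficients[3, 1], tolerance = 1e-10)
    expect_equal(fit$p_tiv[j], ref$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(fit$p_sex[j], ref$coefficients[3, 4], tolerance = 1e-10)
    expect_equal(fit$r2[j], ref$r.squared, tolerance = 1e-10)
    # standardized betas equal coefficients of the z-scored model
    refz <- lm(scale(y) ~ scale(co$tiv) + scale(sex))
    expect_equal(fit$beta_tiv[j], unname(coef(refz)[2]), tolerance = 1e-10)
    expect_equal(fit$beta_sex[j], unname(coef(refz)[3]), tolerance = 1e-10)
    expect_equal(fit$d_sex[j], fit$b_sex[j] / sd(y))
  }
  expect_true(all(abs(fit$sr_tiv) <= 1 & abs(fit$sr_sex) <= 1))
})

test_that("covariate regression is null-behaved when sex is unrelated to volume", {
  ps <- sapply(1:40, function(s) {
    set.seed(400 + s)
    n <- 40
    d <- data.frame(subject_id = sprintf("n%02d", 1:n),
                    group = rep(c("F", "M"), each = n / 2),
                    tiv = rnorm(n, 1500, 80))
    d$Insula_L <- 0.004 * d$tiv + rnorm(n, 0, 0.3)  # no sex effect
    fit_covariate_regression(cohort_table(d))$p_sex
  })
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.07)
  ks <- ks.test(ps, "punif")$p.value
  expect_gt(ks, 0.01)
})

test_that("semi-partial correlations follow the t-statistic identity", {
  co <- toy_cohort(10, 10, p = 2, seed = 17)
  fit <- fit_covariate_regression(co)
  sex <- as.numeric(co$group == "M")
  for (j in seq_along(fit$voi)) {
    y <- co[[fit$voi[j]]]
    full <- summary(lm(y ~ co$tiv + sex))$r.squared
    drop_sex <- summary(lm(y ~ co$tiv))$r.squared
    drop_tiv <- summary(lm(y ~ sex))$r.squared
    expect_equal(fit$sr_sex[j]^2, full - drop_sex, tolerance = 1e-10)
    expect_equal(fit$sr_tiv[j]^2, full - drop_tiv, tolerance = 1e-10)
  }
})
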