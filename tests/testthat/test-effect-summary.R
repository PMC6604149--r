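test_that("replication scoring applies the all-or-all-but-one rule", {
  codes <- rbind(a = c(1L, 1L, 0L, 0L), b = c(1L, -1L, 0L, 0L),
                 c = c(1L, 1L, 0L, 1L), d = c(1L, 1L, 0L, 0L))
  colnames(codes) <- paste0("v", 1:4)
  out <- replication_scores(codes)
  expect_equal(out$score, c(4L, 2L, 0L, 1L))
  # unanimity and one-dissent both replicate; mixed signs do not
  expect_equal(out$replicable, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$sameness, c(FALSE, FALSE, TRUE, FALSE))
  # invariant to dataset ordering
  out2 <- replication_scores(codes[c(3, 1, 4, 2), ])
  expect_equal(out2$score, out$score)
  expect_error(replication_scores(codes[1:2, ]), "3 datasets")
})

test_that("replicable and sameness flags are mutually exclusive and score is bounded", {
  set.seed(71)
  for (rep in 1:10) {
    codes <- matrix(sample(c(-1L, 0L, 1L), 4 * 20, TRUE), 4,
                    dimnames = list(NULL, paste0("v", 1:20)))
    out <- replication_scores(codes)
    expect_true(all(abs(out$score) <= 4))
    expect_false(any(out$replicable & out$sameness))
  }
})

test_that("mean d across datasets feeds the intuitive effect-size columns", {
  codes <- rbind(a = c(1L, 0L), b = c(1L, 0L), c = c(1L, 0L))
  d_vals <- rbind(a = c(0.30, 0.05), b = c(0.25, -0.03), c = c(0.35, 0.01))
  colnames(codes) <- colnames(d_vals) <- c("v1", "v2")
  out <- replication_scores(codes, d_vals)
  expect_equal(out$mean_d, c(0.30, 0.01))
  expect_equal(out$overlap_pct, overlap_from_d(c(0.30, 0.01)))
  expect_equal(out$superiority_pct, superiority_from_d(c(0.30, 0.01)))
})

test_that("overlap matches numerical integration of the minimum density", {
  expect_equal(overlap_from_d(0), 100)
  for (d in c(0.1, 0.22, 0.38, 0.8, 1.6)) {
    ovl <- integrate(function(x) pmin(dnorm(x), dnorm(x, mean = d)),
                     -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(overlap_from_d(d), 100 * ovl, tolerance = 1e-9)
    expect_equal(overlap_from_d(-d), overlap_from_d(d))
  }
  # strictly decreasing in |d|
  ds <- seq(0, 3, by = 0.1)
  expect_true(all(diff(overlap_from_d(ds)) < 0))
  expect_equal(round(overlap_from_d(0.22), 1), 91.2)
})

test_that("superiority matches a Monte-Carlo estimate and its reflection identity", {
  expect_equal(superiority_from_d(0), 50)
  set.seed(73)
  for (d in c(0.22, 0.38, 1)) {
    mc <- mean(rnorm(1e6, mean = d) > rnorm(1e6))
    se <- sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(superiority_from_d(d) / 100 - mc), 3 * se + 1e-6)
    expect_equal(superiority_from_d(-d), 100 - superiority_from_d(d))
  }
  ds <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(superiority_from_d(ds)) > 0))
  expect_equal(round(superiority_from_d(0.38), 1), 60.6)
})

test_that("corrections reproduce hand-executed results on a classic p vector", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(mc_correct(p, "bh")$n_rejected, 2)
  # step-down/step-up by hand: 0.008 * 9 = 0.072 and 0.008 * 10 = 0.08
  # both exceed 0.05, so Holm and Bonferroni stop after the first p
  expect_equal(mc_correct(p, "holm")$n_rejected, 1)
  expect_equal(mc_correct(p, "bonferroni")$n_rejected, 1)
  expect_gte(mc_correct(p, "bky")$n_rejected, mc_correct(p, "bh")$n_rejected)
  # single p value: every method reduces to a plain alpha comparison
  for (m in c("bky", "bh", "holm", "bonferroni")) {
    expect_true(mc_correct(0.04, m)$rejected)
    expect_false(mc_correct(0.06, m)$rejected)
  }
  expect_equal(mc_correct(rep(1, 5), "bky")$n_rejected, 0)
  expect_error(mc_correct(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("rejection sets are nested bonferroni within holm within BH", {
  set.seed(79)
  for (rep in 1:20) {
    p <- runif(50)^sample(1:3, 1)
    r_bh <- mc_correct(p, "bh")$rejected
    r_holm <- mc_correct(p, "holm")$rejected
    r_bonf <- mc_correct(p, "bonferroni")$rejected
    expect_true(all(!r_bonf | r_holm))  # bonferroni subset of holm
    expect_true(all(!r_holm | r_bh))    # holm subset of BH
  }
})

test_that("BKY two-stage matches a direct implementation of the procedure", {
  direct_bky <- function(p, alpha = 0.05) {
    m <- length(p); a1 <- alpha / (1 + alpha)
    bh_reject <- function(p, a) {
      o <- order(p); ps <- p[o]
      k <- which(ps <= seq_len(m) * a / m)
      rej <- logical(m)
      if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
      rej
    }
    r1 <- sum(bh_reject(p, a1))
    if (r1 == 0) return(logical(m))
    if (r1 == m) return(rep(TRUE, m))
    bh_reject(p, a1 * m / (m - r1))
  }
  set.seed(83)
  for (rep in 1:20) {
    p <- runif(30)^sample(1:4, 1)
    expect_equal(mc_correct(p, "bky")$rejected, direct_bky(p))
  }
})

test_that("the correction profile counts are monotone across procedures", {
  set.seed(89)
  stats <- list(strong = runif(60)^4, weak = runif(60))
  prof <- correction_profile(stats)
  expect_equal(prof$dataset, c("strong", "weak"))
  for (i in 1:2) {
    expect_gte(prof$bh[i], prof$holm[i])
    expect_gte(prof$holm[i], prof$bonferroni[i])
    expect_gte(prof$uncorrected[i], prof$bh[i])
  }
  # all-null dataset: no rejections anywhere
  nullp <- correction_profile(list(none = seq(0.5, 0.99, length.out = 30)))
  expect_equal(unlist(nullp[1, -1]), c(uncorrected = 0, bky = 0, bh = 0,
                                       holm = 0, bonferroni = 0))
})
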