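# Small cohorts built by hand for closed-form oracle checks. VOI columns
# reuse AAL region names so the default atlas validates them.

toy_cohort <- function(n_f = 5, n_m = 5, p = 3, seed = 1,
                       tiv_f = 1450, tiv_m = 1570, tiv_sd = 70,
                       rel_sd = 0.08) {
  set.seed(seed)
  n <- n_f + n_m
  tiv <- abs(c(rnorm(n_f, tiv_f, tiv_sd), rnorm(n_m, tiv_m, tiv_sd)))
  vn <- aal116_atlas()$name[seq_len(p)]
  voi <- sapply(seq_len(p), function(j) {
    base <- runif(1, 0.5, 8)
    base * tiv / 1500 * exp(rnorm(n, 0, rel_sd))
  })
  colnames(voi) <- vn
  d <- data.frame(subject_id = sprintf("T%02d", seq_len(n)),
                  group = rep(c("F", "M"), c(n_f, n_m)),
                  tiv = tiv, stringsAsFactors = FALSE)
  cohort_table(cbind(d, as.data.frame(voi)), provenance = "toy")
}

# cohort with explicitly chosen TIVs per group (VOIs filled arbitrarily)
tiv_only_cohort <- function(tiv_f, tiv_m) {
  n <- length(tiv_f) + length(tiv_m)
  d <- data.frame(
    subject_id = sprintf("U%02d", seq_len(n)),
    group = rep(c("F", "M"), c(length(tiv_f), length(tiv_m))),
    tiv = c(tiv_f, tiv_m),
    Precentral_L = c(tiv_f, tiv_m) * 0.005,
    Precentral_R = c(tiv_f, tiv_m) * 0.004,
    stringsAsFactors = FALSE)
  cohort_table(d, provenance = "tiv_only")
}

study_spec <- function(mode = "null_scaling", seed = 1, ...)
  default_generator_spec(mode, seed = seed, ...)
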