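#' Pipeline configuration
#'
#' Collects every knob of the full analysis in one validated object.
#' Exactly one of `input` (a cohort CSV/TSV) or `spec` (a
#' [generator_spec()] used to simulate the cohort) drives the run.
#'
#' @param input Optional path to a cohort table; `NULL` to simulate.
#' @param spec Optional `generator_spec`; defaults to
#'   `default_generator_spec(seed = seed)` when `input` is `NULL`.
#' @param alpha Significance threshold (default 0.05).
#' @param marginal_alpha Marginal reporting threshold (default 0.1).
#' @param caliper TIV-matching caliper in ml (default 10).
#' @param target_d Calibration target for the single-sex splits (default
#'   1.596).
#' @param tolerance Calibration tolerance (default 0.06).
#' @param max_iter Calibration iteration cap (default 10000).
#' @param methods Adjustment methods to run; any of `"proportion"`,
#'   `"pcp"`, `"residuals"`, `"covariate"`.
#' @param corrections Multiplicity corrections for the count profile.
#' @param seed Seed controlling simulation, calibration and bootstrap.
#' @param outdir Optional directory for the CSV outputs; `NULL` keeps the
#'   results in memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, spec = NULL,
                            alpha = 0.05, marginal_alpha = 0.1,
                            caliper = 10, target_d = 1.596,
                            tolerance = 0.06, max_iter = 10000L,
                            methods = c("proportion", "pcp", "residuals",
                                        "covariate"),
                            corrections = c("bky", "bh", "holm",
                                            "bonferroni"),
                            seed = 1L, outdir = NULL) {
  stopifnot(alpha > 0, alpha < marginal_alpha, marginal_alpha < 1,
            caliper > 0)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(input) && is.null(spec))
    spec <- default_generator_spec(seed = seed)
  structure(list(input = input, spec = spec, alpha = alpha,
                 marginal_alpha = marginal_alpha, caliper = caliper,
                 target_d = target_d, tolerance = tolerance,
                 max_iter = as.integer(max_iter), methods = methods,
                 corrections = corrections, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Desk-scale orchestration of the whole study design: obtain a cohort
#' (read or simulate), adjust it with every configured method, build the
#' criterial subsamples (TIV-matched pairs plus calibrated large/small-TIV
#' single-sex splits), compute per-VOI difference statistics and TIV-VOI
#' regression diagnostics everywhere, then summarize cross-method
#' concordance, agreement with the matched criterion, replication scores
#' and the multiplicity-correction count profile. Deterministic given the
#' seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_bundle` with elements `cohort`,
#'   `generator_report`, `datasets`, `stats`, `regressions`,
#'   `slope_correlations`, `match`, `splits`, `concordance`,
#'   `criterion_agreement`, `replication`, `corrections`, and `config`.
#'   When `config$outdir` is set, the tables are also written as CSV.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  alpha <- config$alpha

  gen_report <- NULL
  cohort <- stage("input", {
    if (!is.null(config$input)) read_cohort(config$input)
    else {
      sim <- generate_cohort(config$spec)
      gen_report <- sim$report
      sim$cohort
    }
  })
  stage("validation", check_two_groups(cohort))

  datasets <- stage("adjustment", {
    out <- list(raw = as_adjusted(cohort, "raw"))
    if ("proportion" %in% config$methods)
      out$proportion <- adjust_proportion(cohort)
    if ("pcp" %in% config$methods) out$pcp <- adjust_pcp(cohort)
    if ("residuals" %in% config$methods)
      out$residuals <- adjust_residuals(cohort)
    out
  })
  covariate_fit <- if ("covariate" %in% config$methods)
    stage("covariate_regression", fit_covariate_regression(cohort))

  stats <- stage("voi_stats", {
    out <- lapply(datasets, ttest_by_voi, alpha = alpha,
                  marginal_alpha = config$marginal_alpha)
    if (!is.null(covariate_fit))
      out$covariate <- data.frame(voi = covariate_fit$voi,
                                  p = covariate_fit$p_sex,
                                  d = covariate_fit$d_sex,
                                  stringsAsFactors = FALSE)
    out
  })

  regressions <- stage("tiv_regression",
                       lapply(datasets, tiv_regression))
  slope_cors <- stage("slope_correlations", {
    nm <- intersect(names(regressions), names(stats))
    stats::setNames(lapply(nm, function(k)
      slope_outcome_correlation(regressions[[k]], stats[[k]])), nm)
  })

  match <- stage("tiv_match", tiv_match(cohort, caliper = config$caliper))
  matched_stats <- if (!is.null(match$matched_cohort))
    stage("matched_stats",
          ttest_by_voi(as_adjusted(match$matched_cohort, "raw"),
                       alpha = alpha,
                       marginal_alpha = config$marginal_alpha))

  group_size <- if (nrow(match$pairs) >= 2L) nrow(match$pairs) else NULL
  splits <- stage("calibration", {
    out <- list()
    for (g in c("F", "M")) {
      pool <- subset_cohort(cohort,
                            cohort$subject_id[cohort$group == g],
                            provenance = paste0("only_", g))
      gs <- min(group_size %||% (nrow(pool) %/% 2L), nrow(pool) %/% 2L)
      if (gs >= 2L)
        out[[paste0("only_", g)]] <-
          calibrate_split(pool, group_size = gs,
                          target_d = config$target_d,
                          tolerance = config$tolerance,
                          max_iter = config$max_iter,
                          seed = config$seed + match(g, c("F", "M")))
    }
    out
  })
  split_stats <- stage("split_stats",
    lapply(splits, function(s)
      ttest_by_voi(as_adjusted(s$subsample, "raw"), alpha = alpha,
                   marginal_alpha = config$marginal_alpha)))

  method_names <- setdiff(names(stats), "raw")
  codes <- lapply(stats[method_names], code_differences, alpha = alpha)
  p_tables <- lapply(stats[method_names], function(s)
    stats::setNames(s$p, s$voi))
  concordance <- stage("concordance", list(
    free_kappa = free_marginal_kappa(codes, seed = config$seed),
    kendall_w = kendall_w(p_tables),
    spearman = spearman_matrix(p_tables)))

  criterion <- NULL
  replication <- NULL
  if (!is.null(matched_stats)) {
    crit_codes <- code_differences(matched_stats, alpha = alpha)
    criterion <- stage("criterion_agreement",
      lapply(codes, criterion_agreement, criterion = crit_codes))
    # replication pools the matched criterion with the TIV-free methods
    rep_methods <- intersect(c("covariate", "pcp", "residuals"),
                             names(stats))
    if (length(rep_methods) >= 2L) {
      rep_codes <- c(list(tiv_matched = crit_codes), codes[rep_methods])
      rep_d <- c(list(tiv_matched = stats::setNames(matched_stats$d,
                                                    matched_stats$voi)),
                 lapply(stats[rep_methods], function(s)
                   stats::setNames(s$d, s$voi)))
      replication <- stage("replication",
                           replication_scores(rep_codes, rep_d))
    }
  }

  profile_input <- c(stats,
                     if (!is.null(matched_stats))
                       list(tiv_matched = matched_stats))
  corrections <- stage("correction_profile",
                       correction_profile(profile_input, alpha = alpha,
                                          corrections = config$corrections))

  bundle <- structure(list(cohort = cohort, generator_report = gen_report,
                           datasets = datasets,
                           covariate_fit = covariate_fit,
                           stats = stats, matched_stats = matched_stats,
                           split_stats = split_stats,
                           regressions = regressions,
                           slope_correlations = slope_cors,
                           match = match, splits = splits,
                           concordance = concordance,
                           criterion_agreement = criterion,
                           replication = replication,
                           corrections = corrections,
                           config = config),
                      class = "pipeline_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name)
    utils::write.csv(as.data.frame(x), file.path(outdir,
                                                 paste0(name, ".csv")),
                     row.names = FALSE)
  for (nm in names(bundle$stats))
    if (is.data.frame(bundle$stats[[nm]]))
      wcsv(bundle$stats[[nm]], paste0("stats_", nm))
  for (nm in names(bundle$regressions))
    wcsv(bundle$regressions[[nm]], paste0("tiv_regression_", nm))
  if (!is.null(bundle$matched_stats))
    wcsv(bundle$matched_stats, "stats_tiv_matched")
  if (!is.null(bundle$covariate_fit))
    wcsv(bundle$covariate_fit, "covariate_fit")
  if (!is.null(bundle$match))
    wcsv(bundle$match$pairs, "matched_pairs")
  for (nm in names(bundle$splits)) {
    s <- bundle$splits[[nm]]
    wcsv(data.frame(subject_id = c(s$large_group, s$small_group),
                    pool = rep(c("large", "small"),
                               c(length(s$large_group),
                                 length(s$small_group)))),
         paste0("split_", nm))
  }
  wcsv(bundle$concordance$spearman$rho, "spearman_rho")
  if (!is.null(bundle$replication)) wcsv(bundle$replication, "replication")
  wcsv(bundle$corrections, "correction_profile")
  invisible(NULL)
}

#' Human-readable digest of a pipeline bundle
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of digest lines (also printed).
#' @export
report_summary <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  alpha <- bundle$config$alpha
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  tab <- table(bundle$cohort$group)
  add("Cohort: %d subjects (F=%d, M=%d), %d VOIs",
      nrow(bundle$cohort), tab[["F"]], tab[["M"]],
      length(voi_names(bundle$cohort)))
  for (nm in names(bundle$stats)) {
    s <- bundle$stats[[nm]]
    sig <- sum(s$p < alpha)
    n_mf <- sum(s$p < alpha & s$d > 0)
    n_fm <- sum(s$p < alpha & s$d < 0)
    add("%-12s %3d significant VOIs at alpha=%.2f (M>F: %d, F>M: %d)",
        nm, sig, alpha, n_mf, n_fm)
  }
  if (!is.null(bundle$matched_stats)) {
    s <- bundle$matched_stats
    add("tiv_matched  %3d significant VOIs (pairs: %d)",
        sum(s$p < alpha), nrow(bundle$match$pairs))
  }
  fk <- bundle$concordance$free_kappa
  add("Concordance: free-marginal kappa %.3f [%.3f, %.3f], Kendall W %.3f",
      fk$kappa, fk$ci_low, fk$ci_high, bundle$concordance$kendall_w)
  if (!is.null(bundle$criterion_agreement))
    for (nm in names(bundle$criterion_agreement)) {
      ca <- bundle$criterion_agreement[[nm]]
      add("vs TIV-matched criterion: %-12s kappa %.3f (%s)",
          nm, ca$kappa, ca$band)
    }
  if (!is.null(bundle$replication)) {
    add("Replicable differences: %d of %d VOIs; consistent sameness: %d",
        sum(bundle$replication$replicable), nrow(bundle$replication),
        sum(bundle$replication$sameness))
  } else {
    add("0 replicable differences (replication stage not run)")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
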