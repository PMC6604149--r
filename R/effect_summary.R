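#' Replication scoring across datasets
#'
#' For each VOI, the trinary codes (+1 significant M > F, -1 significant
#' F > M, 0 no significant difference) obtained in several datasets are
#' summed into a signed replication score. A difference is flagged
#' replicable when it appears, with the same sign, in all or all except
#' one of the datasets (`|score| >= n_datasets - 1`); a consistent lack of
#' difference ("sameness") is flagged under the strict criterion
#' score = 0.
#'
#' @param codes Matrix (datasets x VOIs) of trinary codes, or a list of
#'   named code vectors as produced by [code_differences()]. At least 3
#'   datasets are required.
#' @param d_values Optional matrix/list of per-dataset Cohen's d values
#'   over the same VOIs; when given, the per-VOI arithmetic mean d (over
#'   all datasets, significant or not) and its intuitive conversions are
#'   added.
#' @return Data frame with one row per VOI: `score`, `replicable`,
#'   `sameness` and (with `d_values`) `mean_d`, `overlap_pct`,
#'   `superiority_pct`.
#' @export
replication_scores <- function(codes, d_values = NULL) {
  mat <- as_method_matrix(codes)
  n_dat <- nrow(mat)
  if (n_dat < 3L) stop("replication scoring needs at least 3 datasets",
                       call. = FALSE)
  score <- colSums(mat)
  out <- data.frame(voi = colnames(mat) %||% seq_len(ncol(mat)),
                    score = as.integer(score),
                    replicable = abs(score) >= n_dat - 1,
                    sameness = score == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(d_values)) {
    dmat <- as_method_matrix(d_values)
    stopifnot(ncol(dmat) == ncol(mat))
    out$mean_d <- colMeans(dmat)
    out$overlap_pct <- overlap_from_d(out$mean_d)
    out$superiority_pct <- superiority_from_d(out$mean_d)
  }
  out
}

#' Percent of distribution overlap for a standardized difference
#'
#' Overlapping coefficient of two unit-variance normal distributions whose
#' means differ by d: `OVL = 2 * Phi(-|d| / 2)`, expressed in percent.
#' Identical distributions overlap 100%.
#'
#' @param d Cohen's d (vectorized).
#' @return Percent overlap in (0, 100\].
#' @examples
#' overlap_from_d(c(0, 0.22))
#' @export
overlap_from_d <- function(d) 100 * 2 * stats::pnorm(-abs(d) / 2)

#' Percent of superiority (common-language effect size)
#'
#' Probability, in percent, that a random member of the higher-scoring
#' population exceeds a random member of the other:
#' `Phi(d / sqrt(2))`. At d = 0 this is chance (50%), and
#' `superiority(-d) = 100 - superiority(d)`.
#'
#' @param d Cohen's d (vectorized).
#' @return Percent superiority in (0, 100).
#' @examples
#' superiority_from_d(c(0, 0.38))
#' @export
superiority_from_d <- function(d) 100 * stats::pnorm(d / sqrt(2))

#' Multiple-comparison corrections
#'
#' Applies one of four procedures, listed in decreasing order of expected
#' power: the Benjamini-Krieger-Yekutieli two-stage adaptive FDR
#' procedure (`"bky"`), the Benjamini-Hochberg linear step-up (`"bh"`),
#' Holm's step-down (`"holm"`) and the single-step Bonferroni-Dunn
#' correction (`"bonferroni"`). The rejection sets of the last three are
#' always nested: bonferroni within holm within bh.
#'
#' The BKY procedure first runs BH at level `alpha' = alpha / (1 + alpha)`;
#' the number of non-rejections estimates the number of true nulls `m0`,
#' and BH is re-run at level `alpha' * m / m0` (all hypotheses are
#' rejected if the first stage rejects everything).
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param method One of `"bky"`, `"bh"`, `"holm"`, `"bonferroni"`.
#' @param alpha Target level (default 0.05).
#' @return List with `rejected` (logical vector), `n_rejected`, `method`,
#'   `alpha`.
#' @export
mc_correct <- function(p_values, method = c("bky", "bh", "holm",
                                            "bonferroni"),
                       alpha = 0.05) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1 | is.na(p_values)))
    stop("p values must lie in [0, 1]", call. = FALSE)
  rejected <- switch(method,
    bh = stats::p.adjust(p_values, "BH") <= alpha,
    holm = stats::p.adjust(p_values, "holm") <= alpha,
    bonferroni = stats::p.adjust(p_values, "bonferroni") <= alpha,
    bky = bky_reject(p_values, alpha))
  list(rejected = rejected, n_rejected = sum(rejected),
       method = method, alpha = alpha)
}

bky_reject <- function(p, alpha) {
  m <- length(p)
  alpha1 <- alpha / (1 + alpha)
  stage1 <- stats::p.adjust(p, "BH") <= alpha1
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  stats::p.adjust(p, "BH") * m0 / m <= alpha1
}

#' Significant-count profile across corrections
#'
#' Counts, for each dataset, the VOIs that stay significant under no
#' correction and under each multiplicity correction - the summary
#' revealing how strongly each adjusted dataset's differences survive
#' correction.
#'
#' @param stats_by_dataset Named list of `voi_stats` tables (or of p-value
#'   vectors).
#' @param alpha Significance level (default 0.05).
#' @param corrections Character vector of corrections to apply.
#' @return Data frame with one row per dataset and one column per
#'   correction (plus `uncorrected`).
#' @export
correction_profile <- function(stats_by_dataset, alpha = 0.05,
                               corrections = c("bky", "bh", "holm",
                                               "bonferroni")) {
  stopifnot(length(stats_by_dataset) >= 1L)
  get_p <- function(x) if (is.data.frame(x)) x$p else as.numeric(x)
  rows <- lapply(stats_by_dataset, function(x) {
    p <- get_p(x)
    counts <- c(uncorrected = sum(p < alpha),
                vapply(corrections, function(mth)
                  mc_correct(p, mth, alpha)$n_rejected, numeric(1)))
    as.data.frame(as.list(counts))
  })
  out <- do.call(rbind, rows)
  out <- cbind(dataset = names(stats_by_dataset), out)
  rownames(out) <- NULL
  out
}
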