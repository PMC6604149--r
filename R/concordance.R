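#' Trinary difference coding of a stats table
#'
#' Codes each VOI as +1 (significant M > F), -1 (significant F > M) or 0
#' (no significant difference) at the chosen threshold.
#'
#' @param stats A `voi_stats` table (see [ttest_by_voi()]), or any data
#'   frame with columns `voi`, `p` and `d`.
#' @param alpha Significance threshold (default 0.05).
#' @return Named integer vector in \{-1, 0, +1\}, one element per VOI.
#' @export
code_differences <- function(stats, alpha = 0.05) {
  codes <- ifelse(stats$p < alpha, ifelse(stats$d > 0, 1L, -1L), 0L)
  stats::setNames(as.integer(codes), stats$voi)
}

#' Free-marginal multi-rater kappa
#'
#' Chance-corrected nominal agreement among two or more raters (here,
#' adjustment methods) that assumes no fixed category margins:
#' `kappa = (Po - 1/k) / (1 - 1/k)` with `Po` the mean pairwise proportion
#' of agreement across items and `k` the number of categories. Codes are
#' binarized to significant / not significant (k = 2) before computing the
#' index; the confidence interval is a case bootstrap over VOIs.
#'
#' @param codes List of trinary code vectors (one per method), all over
#'   the same VOIs, e.g. from [code_differences()].
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List with `kappa`, `ci_low`, `ci_high`, `overall_agreement`
#'   (percent mean pairwise agreement), `n_raters`, `n_items`.
#' @export
free_marginal_kappa <- function(codes, conf = 0.95, n_boot = 2000L,
                                seed = 1L) {
  if (length(codes) < 2L) stop("need at least 2 raters", call. = FALSE)
  mat <- do.call(cbind, lapply(codes, function(x) as.integer(x != 0L)))
  k <- 2
  kappa_of <- function(m) {
    pairs <- utils::combn(ncol(m), 2)
    po <- mean(apply(pairs, 2, function(pr) mean(m[, pr[1]] == m[, pr[2]])))
    (po - 1 / k) / (1 - 1 / k)
  }
  pairs <- utils::combn(ncol(mat), 2)
  po <- mean(apply(pairs, 2, function(pr) mean(mat[, pr[1]] == mat[, pr[2]])))
  kap <- (po - 1 / k) / (1 - 1 / k)
  with_preserved_seed({
    set.seed(as.integer(seed))
    boot <- replicate(n_boot, {
      idx <- sample.int(nrow(mat), replace = TRUE)
      kappa_of(mat[idx, , drop = FALSE])
    })
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), names = FALSE)
  list(kappa = kap, ci_low = qs[1], ci_high = qs[2],
       overall_agreement = 100 * po,
       n_raters = ncol(mat), n_items = nrow(mat))
}

#' Kendall's coefficient of concordance (W)
#'
#' Ordinal agreement among m rankings with the midrank tie correction.
#' Here p values are the ranked quantity: they put every method and
#' sample on a common standardized scale.
#'
#' @param p_tables Matrix (methods x VOIs) of p values, or a list of
#'   equally named p vectors.
#' @return Kendall's W in \[0, 1\].
#' @export
kendall_w <- function(p_tables) {
  mat <- as_method_matrix(p_tables)
  m <- nrow(mat); n <- ncol(mat)
  if (m < 2L) stop("need at least 2 methods", call. = FALSE)
  ranks <- t(apply(mat, 1, rank))           # midranks for ties
  r_sum <- colSums(ranks)
  s <- sum((r_sum - m * (n + 1) / 2)^2)
  # tie correction: sum over raters of sum(t^3 - t) per tied group
  tie <- sum(apply(ranks, 1, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie
  if (denom <= 0) return(0)
  12 * s / denom
}

#' Pairwise Spearman correlation matrix of p-value orderings
#'
#' @param p_tables Matrix (methods x VOIs) of p values, or a named list of
#'   p vectors.
#' @return List with `rho` and `p` (method x method matrices; the
#'   diagonal of `rho` is 1).
#' @export
spearman_matrix <- function(p_tables) {
  mat <- as_method_matrix(p_tables)
  m <- nrow(mat)
  rho <- diag(1, m); pv <- matrix(NA_real_, m, m)
  dimnames(rho) <- dimnames(pv) <- list(rownames(mat), rownames(mat))
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    ct <- suppressWarnings(
      stats::cor.test(mat[i, ], mat[j, ], method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  list(rho = rho, p = pv)
}

as_method_matrix <- function(p_tables) {
  if (is.list(p_tables) && !is.data.frame(p_tables)) {
    nm <- lapply(p_tables, names)
    if (!all(vapply(nm, identical, logical(1), nm[[1]])))
      stop("methods cover different VOI sets", call. = FALSE)
    p_tables <- do.call(rbind, p_tables)
  }
  as.matrix(p_tables)
}

#' Agreement of a candidate coding with a criterion coding
#'
#' Compares the trinary difference codes of an adjusted dataset with those
#' of a criterion dataset (typically the TIV-matched subsample) using
#' unweighted Cohen's kappa, an asymptotic confidence interval, the
#' Landis-Koch verbal band, and the hit taxonomy:
#' \describe{
#'   \item{hits_sig}{significant differences of the same sign in both}
#'   \item{hits_null}{no significant difference in either}
#'   \item{false_pos}{significant in the candidate only}
#'   \item{false_neg}{significant in the criterion only}
#'   \item{reversions}{significant in both with opposite signs}
#' }
#' The five counts always partition the VOI set.
#'
#' @param candidate,criterion Trinary code vectors over the same VOIs.
#' @param conf Confidence level (default 0.95).
#' @return List with `kappa`, `ci_low`, `ci_high`, `p` (test of kappa = 0),
#'   `band`, and `taxonomy` (named counts).
#' @export
criterion_agreement <- function(candidate, criterion, conf = 0.95) {
  if (length(candidate) != length(criterion))
    stop("code vectors differ in length", call. = FALSE)
  lev <- c(-1L, 0L, 1L)
  a <- factor(candidate, levels = lev)
  b <- factor(criterion, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kap <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  se <- if (pe == 1) 0 else sqrt(po * (1 - po) / (n * (1 - pe)^2))
  # null SE (kappa = 0) for the significance test
  se0 <- if (pe == 1) 0 else sqrt(pe / (n * (1 - pe)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- if (se0 == 0) NA_real_ else
    2 * stats::pnorm(-abs(kap / se0))
  taxonomy <- c(
    hits_sig = sum(candidate == criterion & criterion != 0L),
    hits_null = sum(candidate == 0L & criterion == 0L),
    false_pos = sum(candidate != 0L & criterion == 0L),
    false_neg = sum(candidate == 0L & criterion != 0L),
    reversions = sum(candidate != 0L & criterion != 0L &
                       candidate != criterion))
  list(kappa = kap, ci_low = kap - z * se, ci_high = kap + z * se,
       p = p, band = landis_koch_band(kap), taxonomy = taxonomy)
}

#' Landis-Koch verbal band for a kappa value
#'
#' @param kappa Agreement index.
#' @return `"poor"` (< 0), `"slight"` (0-0.20), `"fair"` (0.21-0.40),
#'   `"moderate"` (0.41-0.60), `"substantial"` (0.61-0.80) or
#'   `"almost perfect"` (0.81-1).
#' @export
landis_koch_band <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}
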