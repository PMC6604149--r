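#' TIV-adjustment methods
#'
#' Four procedures to remove total-intracranial-volume (head size) scaling
#' effects from regional volumes before comparing groups:
#' \describe{
#'   \item{proportion}{`VOIadj = VOI / TIV`. Implicitly assumes a strictly
#'     proportional VOI-TIV relationship (allometric exponent b = 1).}
#'   \item{power-corrected proportion (PCP)}{`VOIadj = VOI / TIV^b`, with b
#'     the slope of the whole-sample OLS regression of log(VOI) on
#'     log(TIV). Correct when volumes scale as a power law of TIV.}
#'   \item{residuals}{`VOIadj = VOI - b (TIV - mean(TIV))`, with b the
#'     whole-sample OLS slope of VOI on TIV. Removes the linear TIV effect
#'     while keeping adjusted values in ml on the original scale.}
#'   \item{covariate regression}{`VOI = b0 + b_tiv TIV + b_sex sex + e`.
#'     Does not produce adjusted volumes; the sex coefficient estimates the
#'     TIV-free group effect directly (see
#'     [fit_covariate_regression()]).}
#' }
#' All fits pool the two groups (whole-sample estimation). Adjusted tables
#' keep the cohort structure and carry the method label and fitted
#' parameters, so every downstream statistic can be computed on raw or
#' adjusted data alike. Externally adjusted tables (e.g., image-space
#' corrections performed upstream) can be wrapped with
#' `as_adjusted(cohort, "external")`.
#'
#' @name tiv_adjustment
NULL

new_adjusted <- function(cohort, method, fit_params = NULL) {
  structure(as.data.frame(cohort),
            atlas = attr(cohort, "atlas"),
            voi_names = attr(cohort, "voi_names"),
            covariate_names = attr(cohort, "covariate_names"),
            provenance = attr(cohort, "provenance"),
            method = method, fit_params = fit_params,
            class = c("adjusted_dataset", "cohort_table", "data.frame"))
}

#' Tag a cohort as a (possibly externally) adjusted dataset
#'
#' @param cohort A `cohort_table` whose VOI columns already hold the values
#'   to analyze.
#' @param method `"raw"` for unadjusted volumes or `"external"` for an
#'   adjustment performed outside the package.
#' @return An `adjusted_dataset`.
#' @export
as_adjusted <- function(cohort, method = c("raw", "external")) {
  method <- match.arg(method)
  new_adjusted(cohort, method)
}

#' @export
print.adjusted_dataset <- function(x, ...) {
  cat(sprintf("<adjusted_dataset: %s> %d subjects, %d VOIs\n",
              attr(x, "method"), nrow(x), length(attr(x, "voi_names"))))
  invisible(x)
}

#' Adjustment method of a dataset
#' @param dataset An `adjusted_dataset`.
#' @return Character scalar.
#' @export
adjustment_method <- function(dataset) attr(dataset, "method") %||% "raw"

#' Fitted adjustment parameters of a dataset
#' @param dataset An `adjusted_dataset`.
#' @return Method-specific per-VOI parameter table (`NULL` for
#'   raw/proportion/external).
#' @export
fit_params <- function(dataset) attr(dataset, "fit_params")

#' Proportion adjustment
#'
#' Divides every regional volume by the subject's TIV, yielding
#' dimensionless ratios. No parameters are fitted.
#'
#' @param cohort A `cohort_table`.
#' @return An `adjusted_dataset` with method `"proportion"`.
#' @export
adjust_proportion <- function(cohort) {
  v <- voi_matrix(cohort) / cohort$tiv
  new_adjusted(set_voi_matrix(cohort, v), "proportion")
}

#' Fit per-VOI allometric exponents
#'
#' Whole-sample OLS of log(VOI) on log(TIV) for each region. The slope `b`
#' is the allometric exponent used by the power-corrected proportion
#' adjustment; it is invariant to the logarithm base (natural logs are
#' used, and the intercept is stored in natural-log units).
#'
#' @param cohort A `cohort_table` with strictly positive volumes.
#' @return Data frame with columns `voi`, `b`, `intercept`.
#' @export
fit_pcp <- function(cohort) {
  v <- voi_matrix(cohort)
  if (any(v <= 0))
    stop("PCP fitting requires strictly positive volumes; exclude ",
         "zero-volume observations first", call. = FALSE)
  f <- ols_columns(log(cohort$tiv), log(v))
  data.frame(voi = voi_names(cohort), b = f$slope, intercept = f$intercept,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Power-corrected proportion adjustment
#'
#' Divides each volume by TIV raised to the region's fitted allometric
#' exponent, `VOIadj = VOI / TIV^b`.
#'
#' @param cohort A `cohort_table`.
#' @param fits Per-VOI exponents as returned by [fit_pcp()]; by default
#'   fitted on `cohort` itself (re-fit within the analyzed sample).
#' @return An `adjusted_dataset` with method `"pcp"`; `fit_params(x)` holds
#'   the exponents.
#' @export
adjust_pcp <- function(cohort, fits = fit_pcp(cohort)) {
  vn <- voi_names(cohort)
  idx <- match(vn, fits$voi)
  if (anyNA(idx))
    stop("missing PCP fit for VOI(s): ",
         paste(vn[is.na(idx)], collapse = ", "), call. = FALSE)
  b <- fits$b[idx]
  v <- voi_matrix(cohort) / outer(cohort$tiv, b, `^`)
  new_adjusted(set_voi_matrix(cohort, v), "pcp", fits[idx, , drop = FALSE])
}

#' Residuals adjustment
#'
#' Removes the linear TIV effect: `VOIadj = VOI - b (TIV - mean(TIV))`,
#' with the slope and the TIV mean computed over the whole sample (there is
#' no control group in a sex-differences design). Adjusted values stay in
#' ml, keep their raw per-VOI means, and are exactly uncorrelated with TIV.
#'
#' @param cohort A `cohort_table`.
#' @return An `adjusted_dataset` with method `"residuals"`; `fit_params(x)`
#'   holds per-VOI slopes and the grand TIV mean.
#' @export
adjust_residuals <- function(cohort) {
  tiv <- cohort$tiv
  if (stats::sd(tiv) == 0)
    stop("degenerate design: TIV is constant across the sample",
         call. = FALSE)
  v <- voi_matrix(cohort)
  f <- ols_columns(tiv, v)
  tiv_mean <- mean(tiv)
  adj <- v - outer(tiv - tiv_mean, f$slope)
  params <- data.frame(voi = voi_names(cohort), b = f$slope,
                       tiv_mean = tiv_mean, row.names = NULL,
                       stringsAsFactors = FALSE)
  new_adjusted(set_voi_matrix(cohort, adj), "residuals", params)
}

#' Covariate regression of volumes on TIV and sex
#'
#' Fits, for every region, the two-predictor model
#' `VOI = b0 + b_tiv TIV + b_sex sex + e` with sex coded 0 = F, 1 = M, so
#' a positive sex coefficient means larger male volumes. Because TIV and
#' sex compete for variance, `b_sex` estimates the group effect free of
#' head-size scaling; no adjusted dataset is produced.
#'
#' The standardized effect `d_sex` divides `b_sex` by the VOI's standard
#' deviation: whole-sample SD by default, or the pooled within-group SD
#' with `sd = "pooled"`.
#'
#' @param cohort A `cohort_table` with both groups present.
#' @param sd Which VOI standard deviation scales `d_sex`.
#' @return Data frame with one row per VOI: unstandardized coefficients
#'   (`b0`, `b_tiv`, `b_sex`), standardized coefficients (`beta_tiv`,
#'   `beta_sex`), semi-partial correlations (`sr_tiv`, `sr_sex`),
#'   coefficient p values (`p_tiv`, `p_sex`), `d_sex`, and the model `r2`.
#' @export
fit_covariate_regression <- function(cohort, sd = c("whole", "pooled")) {
  sd <- match.arg(sd)
  check_two_groups(cohort)
  n <- nrow(cohort)
  if (n <= 3L) stop("covariate regression needs n > 3", call. = FALSE)
  tiv <- cohort$tiv
  if (stats::sd(tiv) == 0)
    stop("degenerate design: TIV is constant across the sample",
         call. = FALSE)
  sex <- as.numeric(cohort$group == "M")
  y <- voi_matrix(cohort)
  x <- cbind(1, tiv, sex)
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)            # 3 x p
  resid <- y - x %*% beta
  df <- n - 3L
  s2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(xtx_inv), s2))           # 3 x p
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)

  sd_y_whole <- apply(y, 2, stats::sd)
  sd_y <- if (sd == "whole") sd_y_whole else pooled_sd_matrix(y, cohort$group)
  tss <- colSums(scale(y, scale = FALSE)^2)
  r2 <- 1 - colSums(resid^2) / tss
  # semi-partial correlation from the coefficient t: sr^2 = t^2 (1-R^2)/df
  sr <- function(row) sign(tval[row, ]) *
    sqrt(pmin(1, tval[row, ]^2 * (1 - r2) / df))

  data.frame(voi = voi_names(cohort),
             b0 = beta[1, ], b_tiv = beta[2, ], b_sex = beta[3, ],
             beta_tiv = beta[2, ] * stats::sd(tiv) / sd_y_whole,
             beta_sex = beta[3, ] * stats::sd(sex) / sd_y_whole,
             sr_tiv = sr(2), sr_sex = sr(3),
             p_tiv = pval[2, ], p_sex = pval[3, ],
             d_sex = beta[3, ] / sd_y, r2 = r2,
             row.names = NULL, stringsAsFactors = FALSE)
}

# vectorized simple OLS of each column of y on x
ols_columns <- function(x, y) {
  if (stats::sd(x) == 0)
    stop("degenerate design: predictor is constant", call. = FALSE)
  xc <- x - mean(x)
  slope <- colSums(xc * y) / sum(xc^2)
  intercept <- colMeans(y) - slope * mean(x)
  list(slope = slope, intercept = intercept)
}

pooled_sd_matrix <- function(y, group) {
  g <- split(seq_len(nrow(y)), group)
  n1 <- length(g[[1]]); n2 <- length(g[[2]])
  v1 <- apply(y[g[[1]], , drop = FALSE], 2, stats::var)
  v2 <- apply(y[g[[2]], , drop = FALSE], 2, stats::var)
  sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
}
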