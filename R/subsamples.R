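#' TIV-matched cross-group pairing
#'
#' Builds the matched criterial subsample: each female is paired with the
#' male whose TIV is nearest, accepting a pair only if the TIV difference
#' is at most `caliper` ml. The default greedy algorithm repeatedly takes
#' the smallest-difference admissible cross-group pair among still
#' unmatched subjects, which is deterministic given the input (ties broken
#' by subject identifier order) and invariant to row order. Matching on
#' TIV is the one adjustment-free way to remove head-size variation, so
#' the matched subsample serves as the benchmark ("ground truth") for
#' TIV-free group differences.
#'
#' `method = "exact"` searches exhaustively for the pairing that maximizes
#' the number of pairs and, among those, minimizes the total TIV
#' difference. It is intended for verification on small cohorts (at most
#' 10 subjects per group).
#'
#' @param cohort A `cohort_table` with both groups present.
#' @param caliper Maximum admissible TIV difference in ml (default 10).
#' @param method `"greedy"` (default) or `"exact"`.
#' @return A list of class `match_result`: `pairs` (data frame
#'   `subject_id_f`, `subject_id_m`, `tiv_diff`), `matched_cohort` (a
#'   `cohort_table` with exactly the paired subjects), and `unmatched`
#'   (subject ids left out). An empty pairing is a valid result.
#' @export
tiv_match <- function(cohort, caliper = 10, method = c("greedy", "exact")) {
  method <- match.arg(method)
  check_two_groups(cohort, min_per_group = 1L)
  f <- cohort[cohort$group == "F", c("subject_id", "tiv")]
  m <- cohort[cohort$group == "M", c("subject_id", "tiv")]
  cand <- expand.grid(fi = seq_len(nrow(f)), mi = seq_len(nrow(m)))
  cand$diff <- abs(f$tiv[cand$fi] - m$tiv[cand$mi])
  cand <- cand[cand$diff <= caliper, , drop = FALSE]
  pairs <- if (method == "greedy") {
    greedy_pairs(cand, f, m)
  } else {
    if (nrow(f) > 10 || nrow(m) > 10)
      stop("exact matching is exhaustive; limited to 10 subjects per group",
           call. = FALSE)
    exact_pairs(cand, f, m)
  }
  matched_ids <- c(pairs$subject_id_f, pairs$subject_id_m)
  matched <- if (length(matched_ids))
    subset_cohort(cohort, matched_ids, provenance = "tiv_matched")
  else NULL
  structure(list(pairs = pairs,
                 matched_cohort = matched,
                 unmatched = setdiff(cohort$subject_id, matched_ids),
                 caliper = caliper, method = method),
            class = "match_result")
}

greedy_pairs <- function(cand, f, m) {
  cand <- cand[order(cand$diff, f$subject_id[cand$fi], m$subject_id[cand$mi]),
               , drop = FALSE]
  used_f <- logical(nrow(f)); used_m <- logical(nrow(m))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fi <- cand$fi[i]; mi <- cand$mi[i]
    if (!used_f[fi] && !used_m[mi]) {
      keep[i] <- TRUE
      used_f[fi] <- TRUE; used_m[mi] <- TRUE
    }
  }
  sel <- cand[keep, , drop = FALSE]
  data.frame(subject_id_f = f$subject_id[sel$fi],
             subject_id_m = m$subject_id[sel$mi],
             tiv_diff = sel$diff,
             row.names = NULL, stringsAsFactors = FALSE)
}

# exhaustive search: maximize pair count, then minimize total difference
exact_pairs <- function(cand, f, m) {
  best <- list(count = -1L, total = Inf, rows = integer(0))
  n_cand <- nrow(cand)
  recurse <- function(i, used_f, used_m, rows, total) {
    if (i > n_cand) {
      count <- length(rows)
      if (count > best$count ||
          (count == best$count && total < best$total))
        best <<- list(count = count, total = total, rows = rows)
      return(invisible())
    }
    # upper bound prune: even taking all remaining pairs cannot win
    if (length(rows) + (n_cand - i + 1L) < best$count) return(invisible())
    fi <- cand$fi[i]; mi <- cand$mi[i]
    if (!used_f[fi] && !used_m[mi]) {
      used_f[fi] <- TRUE; used_m[mi] <- TRUE
      recurse(i + 1L, used_f, used_m, c(rows, i), total + cand$diff[i])
      used_f[fi] <- FALSE; used_m[mi] <- FALSE
    }
    recurse(i + 1L, used_f, used_m, rows, total)
  }
  recurse(1L, logical(nrow(f)), logical(nrow(m)), integer(0), 0)
  sel <- cand[best$rows, , drop = FALSE]
  sel <- sel[order(sel$diff, f$subject_id[sel$fi]), , drop = FALSE]
  data.frame(subject_id_f = f$subject_id[sel$fi],
             subject_id_m = m$subject_id[sel$mi],
             tiv_diff = sel$diff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (caliper %g ml, %s), %d unmatched\n",
              nrow(x$pairs), x$caliper, x$method, length(x$unmatched)))
  invisible(x)
}

#' Calibrated large/small-TIV split of a single-sex pool
#'
#' Builds one of the single-sex criterial subsamples: subjects are sorted
#' by TIV and median-split into a small-TIV and a large-TIV pool;
#' `group_size` subjects are drawn from each pool, and a stochastic local
#' search (random within-pool replacements and between-pool permutations,
#' accepting only moves that bring the realized standardized TIV
#' difference closer to `target_d`) iterates until the pooled-SD Cohen's d
#' between the selected large and small groups is within `tolerance` of
#' the target or `max_iter` proposals have been made. Comparing the
#' resulting groups estimates pure head-size effects, free of any sex
#' effect.
#'
#' @param cohort A `cohort_table` containing subjects of one group only.
#' @param group_size Number of subjects per selected group (default 74).
#' @param target_d Target standardized TIV difference (default 1.596, the
#'   magnitude separating male and female TIV distributions).
#' @param tolerance Convergence tolerance on |achieved d - target|
#'   (default 0.06).
#' @param max_iter Maximum proposals (default 10000).
#' @param seed RNG seed; fixes the result.
#' @return A list of class `calibrated_split`: `large_group` and
#'   `small_group` (subject ids), `achieved_d`, `iterations`, `converged`,
#'   `seed`, and `subsample` - a `cohort_table` holding the selected
#'   subjects with group recoded to `"M"` for the large-TIV and `"F"` for
#'   the small-TIV group, so that all downstream two-group statistics
#'   apply unchanged (positive d then means large > small).
#' @export
calibrate_split <- function(cohort, group_size = 74L, target_d = 1.596,
                            tolerance = 0.06, max_iter = 10000L, seed = 1L) {
  if (nlevels(droplevels(cohort$group)) != 1L)
    stop("calibrate_split expects a single-group cohort", call. = FALSE)
  n <- nrow(cohort)
  if (2L * group_size > n)
    stop("insufficient subjects: need 2 * group_size <= n", call. = FALSE)
  ord <- order(cohort$tiv, cohort$subject_id)
  ids <- cohort$subject_id[ord]
  tiv <- cohort$tiv[ord]
  names(tiv) <- ids
  half <- n %/% 2L
  small_pool <- ids[seq_len(half)]
  large_pool <- ids[seq.int(n - half + 1L, n)]  # middle subject unused if odd
  if (group_size > half)
    stop("group_size exceeds pool size after the median split",
         call. = FALSE)

  split_d <- function(lg, sg) {
    sp <- sqrt(((length(lg) - 1) * stats::var(tiv[lg]) +
                (length(sg) - 1) * stats::var(tiv[sg])) /
               (length(lg) + length(sg) - 2))
    diff <- mean(tiv[lg]) - mean(tiv[sg])
    if (sp == 0) {
      if (diff == 0) 0 else sign(diff) * Inf  # constant pools
    } else diff / sp
  }

  with_preserved_seed({
    set.seed(as.integer(seed))
    large <- sample(large_pool, group_size)
    small <- sample(small_pool, group_size)
    cur_d <- split_d(large, small)
    it <- 0L
    while (abs(cur_d - target_d) > tolerance && it < max_iter) {
      it <- it + 1L
      if (stats::runif(1) < 0.5) {
        # within-pool replacement
        if (stats::runif(1) < 0.5) {
          pool <- large_pool; sel <- large
        } else {
          pool <- small_pool; sel <- small
        }
        out_pool <- setdiff(pool, sel)
        if (!length(out_pool)) next
        drop_id <- sample(sel, 1L); add_id <- sample(out_pool, 1L)
        new_sel <- c(setdiff(sel, drop_id), add_id)
        if (identical(pool, large_pool)) {
          new_d <- split_d(new_sel, small)
          if (abs(new_d - target_d) < abs(cur_d - target_d)) {
            large <- new_sel; cur_d <- new_d
          }
        } else {
          new_d <- split_d(large, new_sel)
          if (abs(new_d - target_d) < abs(cur_d - target_d)) {
            small <- new_sel; cur_d <- new_d
          }
        }
      } else {
        # between-pool permutation: exchange members of the two groups
        a <- sample(large, 1L); b <- sample(small, 1L)
        new_large <- c(setdiff(large, a), b)
        new_small <- c(setdiff(small, b), a)
        new_d <- split_d(new_large, new_small)
        if (abs(new_d - target_d) < abs(cur_d - target_d)) {
          large <- new_large; small <- new_small; cur_d <- new_d
        }
      }
    }
  })
  converged <- abs(cur_d - target_d) <= tolerance

  sub <- subset_cohort(cohort, c(small, large), provenance = "tiv_split")
  sub$group <- factor(ifelse(sub$subject_id %in% large, "M", "F"),
                      levels = c("F", "M"))
  structure(list(large_group = sort(large), small_group = sort(small),
                 achieved_d = cur_d, iterations = it,
                 converged = converged, target_d = target_d,
                 tolerance = tolerance, seed = seed, subsample = sub),
            class = "calibrated_split")
}

#' @export
print.calibrated_split <- function(x, ...) {
  cat(sprintf(
    "<calibrated_split> %d+%d subjects, achieved d = %.3f (target %.3f, %s after %d iterations)\n",
    length(x$large_group), length(x$small_group), x$achieved_d, x$target_d,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
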