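#' Construct a cohort table
#'
#' A cohort table is the universal input of every stage of the pipeline:
#' one row per subject with the subject identifier, the binary group label
#' (sex, `"F"`/`"M"` with `"F"` as reference level), the total intracranial
#' volume (TIV, ml), one column per regional volume of interest (VOI, ml),
#' and optional scalar covariates (e.g., age).
#'
#' All volumes are stored in ml. If the supplied TIVs look like mm^3
#' (median above 100,000), every volume column is rescaled by 1/1000 with a
#' warning; CAT12 emits mm^3 while results are conventionally reported in ml.
#'
#' @param data A data frame with columns `subject_id`, `group`, `tiv`, one
#'   column per VOI named after an atlas region, and any extra columns
#'   treated as covariates.
#' @param atlas A `region_atlas`; VOI columns must be a subset of its names.
#' @param provenance Free-text label recording where the table came from.
#' @return A data frame of class `cohort_table` with attributes `atlas`,
#'   `voi_names` (in atlas order) and `provenance`.
#' @examples
#' atlas <- aal116_atlas()
#' d <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
#'                 group = c("F", "F", "M", "M"),
#'                 tiv = c(1400, 1450, 1550, 1600),
#'                 Amygdala_L = c(1.5, 1.6, 1.7, 1.8),
#'                 Amygdala_R = c(1.6, 1.7, 1.8, 1.9))
#' cohort <- cohort_table(d, atlas)
#' @export
cohort_table <- function(data, atlas = aal116_atlas(), provenance = "user") {
  stopifnot(is.data.frame(data))
  atlas <- validate_atlas(as.data.frame(atlas))
  mandatory <- c("subject_id", "group", "tiv")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols))
    stop("input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id))
    stop("duplicated subject_id values", call. = FALSE)
  data$group <- normalize_group(data$group)

  other <- setdiff(names(data), mandatory)
  voi_names <- atlas$name[atlas$name %in% other]  # atlas order
  covariate_names <- setdiff(other, voi_names)
  if (!length(voi_names))
    stop("no VOI columns found: column names must match atlas region names",
         call. = FALSE)

  num_cols <- c("tiv", voi_names)
  for (cn in num_cols) data[[cn]] <- as.numeric(data[[cn]])
  if (anyNA(data[num_cols]))
    stop("missing TIV/VOI values are not allowed", call. = FALSE)

  # mm^3 -> ml auto-detection (CAT12 native units)
  if (stats::median(data$tiv) > 1e5) {
    warning("TIV median exceeds 100,000: input interpreted as mm^3 and ",
            "rescaled to ml", call. = FALSE)
    for (cn in num_cols) data[[cn]] <- data[[cn]] / 1000
  }

  bad_tiv <- data$subject_id[data$tiv <= 0]
  if (length(bad_tiv))
    stop("non-positive TIV for subject(s): ",
         paste(bad_tiv, collapse = ", "), call. = FALSE)
  for (cn in voi_names) {
    bad <- data$subject_id[data[[cn]] < 0]
    if (length(bad))
      stop("negative volume in ", cn, " for subject(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    over <- data$subject_id[data[[cn]] >= data$tiv]
    if (length(over))
      stop("VOI ", cn, " not smaller than TIV for subject(s): ",
           paste(over, collapse = ", "), call. = FALSE)
  }

  data <- data[, c(mandatory, voi_names, sort(covariate_names)), drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            atlas = atlas, voi_names = voi_names,
            covariate_names = sort(covariate_names),
            provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

normalize_group <- function(group, levels = c("F", "M")) {
  g <- as.character(group)
  if (!all(g %in% levels)) {
    u <- sort(unique(g))
    if (length(u) != 2L)
      stop("group must have exactly two levels; got: ",
           paste(u, collapse = ", "), call. = FALSE)
    # remap an arbitrary two-level labelling; first sorted level -> reference
    g <- levels[match(g, u)]
  }
  factor(g, levels = levels)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%s), %d VOIs [%s]\n",
              nrow(x),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", "),
              length(attr(x, "voi_names")), attr(x, "provenance")))
  invisible(x)
}

#' Extract the VOI matrix of a cohort
#'
#' @param cohort A `cohort_table` or `adjusted_dataset`.
#' @return Numeric matrix, subjects x VOIs, columns in atlas order.
#' @export
voi_matrix <- function(cohort) {
  vn <- attr(cohort, "voi_names")
  m <- as.matrix(as.data.frame(cohort)[, vn, drop = FALSE])
  rownames(m) <- cohort$subject_id
  m
}

#' Names of the VOI columns of a cohort
#' @param cohort A `cohort_table` or `adjusted_dataset`.
#' @return Character vector in atlas order.
#' @export
voi_names <- function(cohort) attr(cohort, "voi_names")

#' Replace the VOI values of a cohort, keeping its metadata
#' @keywords internal
set_voi_matrix <- function(cohort, values) {
  vn <- attr(cohort, "voi_names")
  stopifnot(is.matrix(values), ncol(values) == length(vn))
  for (j in seq_along(vn)) cohort[[vn[j]]] <- values[, j]
  cohort
}

#' Read a cohort table from delimited text
#'
#' Reads a CSV or TSV file (delimiter inferred from the extension, or
#' supplied) with a header naming `subject_id`, `group`, `tiv` and one
#' column per atlas region; any other column is routed to covariates.
#' Column order in the file is irrelevant.
#'
#' @param path Path to the delimited text file.
#' @param atlas A `region_atlas` (default the packaged AAL-116).
#' @param sep Field delimiter; `NULL` infers `","` unless the file extension
#'   is `.tsv`/`.txt`, which select tab.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, atlas = aal116_atlas(), sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  data <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = c(subject_id = "character",
                                           group = "character"))
  cohort_table(data, atlas = atlas, provenance = basename(path))
}

#' Write a cohort table to delimited text
#'
#' Columns are emitted in a deterministic order: `subject_id`, `group`,
#' `tiv`, VOIs in atlas order, then covariates alphabetically. Numeric
#' fields are written with full precision so that a read/write round trip
#' is lossless.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path; extension selects the delimiter as in
#'   [read_cohort()].
#' @param sep Field delimiter; `NULL` infers from the extension.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  stopifnot(inherits(cohort, "cohort_table") ||
            inherits(cohort, "adjusted_dataset"))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- as.data.frame(cohort)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Keep a subset of subjects
#'
#' @param cohort A `cohort_table`.
#' @param ids Subject identifiers to keep (order follows the cohort).
#' @param provenance Optional new provenance label.
#' @return A `cohort_table` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids, provenance = NULL) {
  stopifnot(all(ids %in% cohort$subject_id))
  keep <- cohort$subject_id %in% ids
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  rebuild_cohort(out, cohort,
                 provenance %||% paste0(attr(cohort, "provenance"), "/subset"))
}

# reattach cohort metadata after base-R data.frame manipulation
rebuild_cohort <- function(data, template, provenance = NULL) {
  structure(data,
            atlas = attr(template, "atlas"),
            voi_names = attr(template, "voi_names"),
            covariate_names = attr(template, "covariate_names"),
            provenance = provenance %||% attr(template, "provenance"),
            class = c("cohort_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_two_groups <- function(cohort, min_per_group = 2L) {
  tab <- table(cohort$group)
  if (length(tab) < 2L || any(tab < min_per_group))
    stop("both groups must be present with at least ", min_per_group,
         " subjects each", call. = FALSE)
  invisible(tab)
}
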