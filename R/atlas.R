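#' The AAL-116 region catalogue
#'
#' Returns the packaged Automated Anatomical Labeling (AAL) atlas with its
#' 116 gray-matter regions in standard order. Odd indices are left-hemisphere
#' and even indices right-hemisphere regions, except the eight lobules of the
#' cerebellar vermis (indices 109-116), which are midline structures.
#'
#' @return A data frame of class `region_atlas` with columns `index`
#'   (integer, 1-116), `name` (character, unique region labels such as
#'   `"Amygdala_R"`), and `hemisphere` (`"left"`, `"right"` or `"vermis"`).
#' @examples
#' atlas <- aal116_atlas()
#' atlas[atlas$index == 42, ]
#' @export
aal116_atlas <- function() {
  path <- system.file("extdata", "aal116_atlas.tsv", package = "tivadjust",
                      mustWork = TRUE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  atlas$index <- as.integer(atlas$index)
  validate_atlas(atlas)
}

#' Validate a region atlas
#'
#' Checks the structural invariants of a region catalogue: unique indices
#' and names, and the left/right parity convention for non-vermis entries.
#'
#' @param atlas A data frame with columns `index`, `name`, `hemisphere`.
#' @return The atlas, invisibly classed as `region_atlas`.
#' @keywords internal
validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas),
            all(c("index", "name", "hemisphere") %in% names(atlas)))
  if (anyDuplicated(atlas$index) || anyDuplicated(atlas$name))
    stop("atlas indices and names must be unique", call. = FALSE)
  if (!all(atlas$hemisphere %in% c("left", "right", "vermis")))
    stop("hemisphere must be one of 'left', 'right', 'vermis'", call. = FALSE)
  lat <- atlas$hemisphere != "vermis"
  odd <- atlas$index %% 2L == 1L
  if (!all(ifelse(odd[lat], atlas$hemisphere[lat] == "left",
                  atlas$hemisphere[lat] == "right")))
    stop("odd indices must be left-hemisphere and even right-hemisphere ",
         "for all non-vermis regions", call. = FALSE)
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}
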