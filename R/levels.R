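#' Drug and ethnicity codings
#'
#' `drug_levels()` returns the two drug classes compared by the selection
#' model. `ethnicity_levels()` returns the five recorded self-reported
#' ethnicity categories; `ethnicity_groups()` returns the analysis grouping,
#' in which Mixed and Other are pooled by default because of low numbers
#' (`pool_mixed_other = FALSE` keeps them separate, the sensitivity
#' configuration).
#'
#' @param pool_mixed_other Pool Mixed and Other into one analysis group?
#' @return Character vector of level names.
#' @export
drug_levels <- function() c("SGLT2i", "DPP4i")

#' @rdname drug_levels
#' @export
ethnicity_levels <- function() c("White", "SouthAsian", "Black", "Mixed", "Other")

#' @rdname drug_levels
#' @export
ethnicity_groups <- function(pool_mixed_other = TRUE) {
  if (pool_mixed_other) c("White", "SouthAsian", "Black", "MixedOther")
  else ethnicity_levels()
}

#' Map recorded ethnicity to its analysis group
#'
#' @param ethnicity Character vector of recorded categories
#'   (see [ethnicity_levels()]).
#' @param pool_mixed_other Pool Mixed and Other into `"MixedOther"`?
#' @return Character vector of analysis group labels.
#' @export
ethnicity_group <- function(ethnicity, pool_mixed_other = TRUE) {
  ethnicity <- as.character(ethnicity)
  bad <- setdiff(unique(ethnicity[!is.na(ethnicity)]), ethnicity_levels())
  if (length(bad) > 0) {
    stop("unknown ethnicity categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (pool_mixed_other) {
    ethnicity[ethnicity %in% c("Mixed", "Other")] <- "MixedOther"
  }
  ethnicity
}
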