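#' Code overweight status from a body-silhouette score
#'
#' Self-reported body size on the nine-figure sex-specific silhouette scale is
#' dichotomised into an overweight indicator: score >= 5 for males, >= 4 for
#' females. The same cut-offs apply at every life stage (age 8, puberty,
#' age 30).
#'
#' @param sex character vector, `"son"`/`"male"` or `"daughter"`/`"female"`.
#' @param score integer vector of silhouette scores in 1..9.
#' @return logical vector: `TRUE` if the score meets the overweight cut-off.
#' @export
#' @examples
#' code_overweight_from_silhouette(c("male", "female", "male"), c(5, 4, 4))
code_overweight_from_silhouette <- function(sex, score) {
  if (any(!is.na(score) & (score < 1 | score > 9 | score != floor(score))))
    abort("silhouette scores must be integers in 1..9")
  male <- sex %in% c("male", "son", "father", "m")
  female <- sex %in% c("female", "daughter", "mother", "f")
  if (any(!male & !female & !is.na(sex)))
    abort("`sex` must code male/son or female/daughter")
  cut <- ifelse(male, 5L, 4L)
  score >= cut
}

#' Derive the three-level parental exposure category
#'
#' Overweight flags at the three life stages collapse into the exposure:
#' overweight *before puberty* (at age 8 and/or in puberty), overweight *at
#' age 30 but not before puberty*, or *never* overweight. Categories are
#' exhaustive and mutually exclusive for complete flag triples; rows with any
#' missing flag yield `NA` (callers drop them with a logged reason).
#'
#' @param ow_age8,ow_puberty,ow_age30 logical vectors.
#' @return factor with levels `before_puberty`, `at30_not_before`, `never`.
#' @export
#' @examples
#' derive_exposure_category(TRUE, FALSE, TRUE)   # before_puberty
#' derive_exposure_category(FALSE, FALSE, TRUE)  # at30_not_before
derive_exposure_category <- function(ow_age8, ow_puberty, ow_age30) {
  out <- rep(NA_character_, length(ow_age8))
  complete <- !is.na(ow_age8) & !is.na(ow_puberty) & !is.na(ow_age30)
  before <- complete & (ow_age8 | ow_puberty)
  at30 <- complete & !before & ow_age30
  never <- complete & !before & !at30
  out[before] <- "before_puberty"
  out[at30] <- "at30_not_before"
  out[never] <- "never"
  factor(out, levels = EXPOSURE_LEVELS)
}
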