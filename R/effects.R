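CONTRASTS <- c("before_puberty", "at30_not_before")
EFFECT_NAMES <- c("nde", "nie_m1", "nie_m2", "nie_m1_m2", "total")

#' Decompose the exposure effect into natural direct and indirect parts
#'
#' Converts structural path coefficients into the counterfactual effect
#' decomposition. Because the system is linear on the latent scale with no
#' exposure-mediator interaction, the natural effects are exact path
#' products: with exposure-contrast paths `a` (exposure to latent
#' overweight), `h` (exposure to height) and `c` (exposure to outcome), the
#' natural direct effect is `c`; the indirect effect via overweight only is
#' `a * b1`; via height only is `h * b2`; via the serial
#' overweight-then-height chain is `a * d * b2`; and the total is their sum
#' (exactly additive).
#'
#' @param coefs a [path_coefs()] object for one group, or a fitted
#'   multi-group model from [fit_mediation()] (all groups decomposed).
#' @param contrast exposure contrasts to decompose (default both).
#' @param group group label attached to the rows when `coefs` is a single
#'   `path_coefs`.
#' @param outcome outcomes to decompose (default all in `coefs`).
#' @return tibble with columns `contrast`, `group`, `outcome`, `effect`
#'   (`nde`, `nie_m1`, `nie_m2`, `nie_m1_m2`, `total`) and `estimate`
#'   (outcome units).
#' @export
#' @examples
#' # the published paternal-line sons' paths reproduce the printed
#' # via-height indirect effect on FEV1 of about -144 mL
decompose_effects <- function(coefs, contrast = CONTRASTS, group = "group",
                              outcome = NULL) {
  if (inherits(coefs, "serimed_fit")) {
    return(bind_rows(lapply(names(coefs$groups), function(g)
      decompose_effects(coefs$groups[[g]]$coefficients, contrast = contrast,
                        group = g, outcome = outcome))))
  }
  if (!inherits(coefs, "path_coefs")) abort("coefs must be path_coefs")
  contrast <- match.arg(contrast, CONTRASTS, several.ok = TRUE)
  outcome <- outcome %||% names(coefs$outcomes)
  bad <- setdiff(outcome, names(coefs$outcomes))
  if (length(bad)) abort(paste0("missing outcome coefficients: ", toString(bad)))
  rows <- list()
  d <- coefs$height[["m1_latent"]]
  for (ct in contrast) {
    a <- coefs$mediator[[ct]]
    h <- coefs$height[[ct]]
    for (oc in outcome) {
      o <- coefs$outcomes[[oc]]
      if (any(is.na(c(a, h, d, o[[ct]], o[["m1_latent"]], o[["height_cm"]]))))
        abort(paste0("missing coefficient for contrast ", ct))
      nde <- o[[ct]]
      nie_m1 <- a * o[["m1_latent"]]
      nie_m2 <- h * o[["height_cm"]]
      nie_m1_m2 <- a * d * o[["height_cm"]]
      rows[[length(rows) + 1]] <- tibble(
        contrast = ct, group = group, outcome = oc,
        effect = EFFECT_NAMES,
        estimate = c(nde, nie_m1, nie_m2, nie_m1_m2,
                     nde + nie_m1 + nie_m2 + nie_m1_m2)
      )
    }
  }
  bind_rows(rows)
}

#' Total effect of a decomposition
#'
#' Sums the natural direct and the three path-specific indirect effects;
#' additivity is exact on the latent-linear scale, so this equals the
#' reduced-form exposure coefficient.
#'
#' @param decomp tibble from [decompose_effects()].
#' @return tibble with one `total` row per contrast, group and outcome.
#' @export
total_effect <- function(decomp) {
  decomp |>
    filter(.data$effect != "total") |>
    group_by(.data$contrast, .data$group, .data$outcome) |>
    summarise(estimate = sum(.data$estimate), .groups = "drop") |>
    mutate(effect = "total", .before = "estimate")
}

#' Sons-minus-daughters moderation contrast
#'
#' Componentwise difference of the two groups' effect decompositions; the
#' quantity used to test moderated mediation by offspring sex.
#'
#' @param effects tibble from [decompose_effects()] holding both groups, or
#'   the sons' tibble when `daughters` is given separately.
#' @param daughters optional daughters' tibble (same contrasts/outcomes).
#' @return tibble with columns `contrast`, `outcome`, `effect`, `delta`
#'   (sons minus daughters, outcome units).
#' @export
group_difference <- function(effects, daughters = NULL) {
  if (!is.null(daughters)) {
    effects <- bind_rows(mutate(effects, group = "son"),
                         mutate(daughters, group = "daughter"))
  }
  if (!all(SEX_LEVELS %in% effects$group))
    abort("need both sons' and daughters' effects")
  sons <- filter(effects, .data$group == "son")
  daus <- filter(effects, .data$group == "daughter")
  keys <- c("contrast", "outcome", "effect")
  if (anyDuplicated(sons[keys]) || anyDuplicated(daus[keys]) ||
      nrow(sons) != nrow(daus))
    abort("mismatched contrast/outcome/effect labels between groups")
  wide <- full_join(sons, daus, by = keys, suffix = c("_son", "_daughter"))
  if (anyNA(wide$estimate_son) || anyNA(wide$estimate_daughter))
    abort("mismatched contrast/outcome/effect labels between groups")
  wide |>
    mutate(delta = .data$estimate_son - .data$estimate_daughter) |>
    select("contrast", "outcome", "effect", "delta")
}

#' Classify the mediation pattern
#'
#' Typology used when reading the significance flags of the direct and
#' indirect effects for one pathway: both significant with the same sign is
#' complementary mediation; only the indirect effect significant is
#' indirect-only; only the direct effect is direct-only; anything else is
#' non-mediation.
#'
#' @param direct_sig,indirect_sig,same_sign logical vectors.
#' @return factor with levels `complementary`, `indirect_only`,
#'   `direct_only`, `non_mediation`.
#' @export
classify_mediation <- function(direct_sig, indirect_sig, same_sign = TRUE) {
  n <- max(length(direct_sig), length(indirect_sig), length(same_sign))
  direct_sig <- rep_len(direct_sig, n)
  indirect_sig <- rep_len(indirect_sig, n)
  same_sign <- rep_len(same_sign, n)
  out <- dplyr::case_when(
    direct_sig & indirect_sig & same_sign ~ "complementary",
    indirect_sig & !direct_sig ~ "indirect_only",
    direct_sig & !indirect_sig ~ "direct_only",
    .default = "non_mediation"
  )
  factor(out, levels = c("complementary", "indirect_only", "direct_only",
                         "non_mediation"))
}
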