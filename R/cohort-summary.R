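utils::globalVariables("where")

#' Descriptive summary of a cohort line
#'
#' Builds the descriptive table reported for each analysis line: parent
#' generation (exposure-category and low-education prevalences) and offspring
#' generation (age median/range; height and lung-function means/sd;
#' overweight-before-puberty and ever-smoking prevalences), by offspring sex
#' and in total. Prevalences are `100 * count / group n` rounded half away
#' from zero to one decimal; counts are exact, so exposure-category counts
#' sum to the group size.
#'
#' @param data cohort tibble.
#' @param line `"paternal"` or `"maternal"`; defaults to the single line
#'   present in `data`.
#' @param by include the by-sex breakdown (default `TRUE`).
#' @return tibble with columns `generation`, `variable`, `group`, `n`,
#'   `count`, `prevalence`, `mean`, `sd`, `median`, `min`, `max` (statistics
#'   not applying to a row are `NA`).
#' @export
summarize_cohort <- function(data, line = NULL, by = TRUE) {
  data <- as_tibble(data)
  line <- line %||% as.character(unique(data$line))
  if (length(line) != 1) abort("`data` holds several lines; pick one via `line`")
  data <- filter(data, .data$line == !!line)
  if (nrow(data) == 0) abort(paste0("no records for line '", line, "'"))

  groups <- list(total = data)
  if (by) {
    for (s in SEX_LEVELS) {
      sub <- filter(data, .data$sex == s)
      if (nrow(sub) == 0) abort(paste0("empty group: ", s))
      groups[[s]] <- sub
    }
  }

  one_group <- function(sub, group) {
    parents <- distinct(sub, .data$parent_id, .data$parent_exposure,
                        .data$parent_edu_low)
    n_par <- nrow(parents)
    n_off <- nrow(sub)
    prev_row <- function(generation, variable, count, n) {
      tibble(generation = generation, variable = variable, group = group,
             n = n, count = count,
             prevalence = round_half_away(100 * count / n, 1),
             mean = NA_real_, sd = NA_real_, median = NA_real_,
             min = NA_real_, max = NA_real_)
    }
    num_row <- function(generation, variable, x) {
      tibble(generation = generation, variable = variable, group = group,
             n = n_off, count = NA_real_, prevalence = NA_real_,
             mean = mean(x), sd = sd(x), median = median(x),
             min = min(x), max = max(x))
    }
    bind_rows(
      tibble(generation = "parent", variable = "n_parents", group = group,
             n = n_par, count = n_par, prevalence = NA_real_,
             mean = NA_real_, sd = NA_real_, median = NA_real_,
             min = NA_real_, max = NA_real_),
      prev_row("parent", "edu_low", sum(parents$parent_edu_low), n_par),
      bind_rows(lapply(EXPOSURE_LEVELS, function(lv)
        prev_row("parent", paste0("overweight_", lv),
                 sum(parents$parent_exposure == lv), n_par))),
      tibble(generation = "offspring", variable = "n_offspring", group = group,
             n = n_off, count = n_off, prevalence = NA_real_,
             mean = NA_real_, sd = NA_real_, median = NA_real_,
             min = NA_real_, max = NA_real_),
      num_row("offspring", "age", sub$age),
      num_row("offspring", "height_cm", sub$height_cm),
      num_row("offspring", "fev1_ml", sub$fev1_ml),
      num_row("offspring", "fvc_ml", sub$fvc_ml),
      num_row("offspring", "fev1_fvc_pct", 100 * sub$fev1_ml / sub$fvc_ml),
      prev_row("offspring", "overweight_prepuberty",
               sum(sub$m1_overweight_prepuberty), n_off),
      prev_row("offspring", "ever_smoker", sum(sub$ever_smoker), n_off)
    )
  }

  out <- bind_rows(lapply(names(groups), function(g) one_group(groups[[g]], g)))
  attr(out, "line") <- line
  out
}
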