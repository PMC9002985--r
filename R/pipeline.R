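#' Pipeline configuration
#'
#' Bundles every stage's settings. Exactly one of `input` (a cohort file
#' path) or `params` (generator parameters, with `n_parents`) must be
#' given; `seed` is mandatory and drives generation, bootstrap and
#' sensitivity stages. Configurations can be written to and read from YAML.
#'
#' @param input path to a cohort CSV/TSV, or `NULL` when generating.
#' @param params [`serimed_params`] for the generator, or `NULL`.
#' @param n_parents clusters to generate when `params` is used.
#' @param spec [model_spec()].
#' @param bronchodilator states to analyse: `"pre"`, and optionally also
#'   `"post"` for the post-bronchodilator rerun.
#' @param B bootstrap resamples (shipped default 10,000).
#' @param sensitivity `NULL` to skip, or a list with optional
#'   `beta_grid`, `n_confounders`, `n_sim`, `n_draws`, `n_subjects`.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed.
#' @param verbose emit stage log lines.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, params = NULL, n_parents = 500L,
                            spec = model_spec(), bronchodilator = "pre",
                            B = 10000L, sensitivity = NULL,
                            out_dir = tempfile("serimed-run-"), seed,
                            verbose = TRUE) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (is.null(input) == is.null(params))
    abort("exactly one of `input` and `params` must be supplied")
  bronchodilator <- match.arg(bronchodilator, c("pre", "post"),
                              several.ok = TRUE)
  structure(
    list(input = input, params = params, n_parents = n_parents, spec = spec,
         bronchodilator = bronchodilator, B = check_scalar_count(B, "B"),
         sensitivity = sensitivity, out_dir = out_dir,
         seed = as.integer(seed), verbose = verbose),
    class = "pipeline_config"
  )
}

stage_log <- function(config, stage, ...) {
  if (isTRUE(config$verbose))
    inform(paste0("[", stage, "] ", sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, fit, effect decomposition, cluster bootstrap,
#' optional confounder-sensitivity grid, and report rendering, for each
#' configured bronchodilator state. All stage artifacts plus a manifest
#' (configuration hash, seed, package version) are written under
#' `config$out_dir`. Identical configurations and seeds give identical
#' bundles.
#'
#' @param config [pipeline_config()].
#' @return invisibly, a list with the cohort, per-state fits, effects,
#'   bootstrap summaries, sensitivity grid and the manifest.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e))))
  }
  cohort <- stage("data", {
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$params, config$n_parents, seed = config$seed)
  })
  stage_log(config, "data", "%d offspring of %d parents", nrow(cohort),
            length(unique(cohort$parent_id)))
  for (g in SEX_LEVELS) {
    ng <- sum(cohort$sex == g)
    if (ng < 50)
      warn(sprintf("group %s has only %d offspring", g, ng))
  }
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  states <- list()
  for (bd in config$bronchodilator) {
    spec <- config$spec
    spec$bronchodilator <- bd
    fit <- stage(paste0("fit-", bd), fit_mediation(cohort, spec))
    stage_log(config, paste0("fit-", bd), "logLik %.1f, converged: %s",
              glance(fit)$logLik, glance(fit)$converged)
    effects <- stage(paste0("effects-", bd), decompose_effects(fit))
    boot <- stage(paste0("bootstrap-", bd),
                  bootstrap_effects(cohort, spec, B = config$B,
                                    seed = config$seed, fit = fit))
    stage_log(config, paste0("bootstrap-", bd), "%d/%d refits converged",
              boot$n_successful, boot$B)
    states[[bd]] <- list(fit = fit, effects = effects, boot = boot)
  }

  sens <- NULL
  if (!is.null(config$sensitivity)) {
    sc <- config$sensitivity
    base <- sensitivity_scenario(
      n_subjects = sc$n_subjects %||% 420L,
      n_sim = sc$n_sim %||% 1000L,
      n_draws = sc$n_draws %||% 1000L,
      seed = config$seed
    )
    sens <- stage("sensitivity",
                  run_grid(base, beta_grid = sc$beta_grid %||%
                             c(0, 1, 3, 5, 7, 9),
                           n_confounders = sc$n_confounders %||% c(1L, 2L)))
    readr::write_csv(sens, file.path(config$out_dir, "sensitivity.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("serimed")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("verbose", "out_dir"))]),
    line = config$spec$line,
    bronchodilator = config$bronchodilator,
    B = config$B,
    n_offspring = nrow(cohort)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (bd in names(states))
    write_report(states[[bd]], config$out_dir, suffix = bd)
  out <- list(cohort = cohort, states = states, sensitivity = sens,
              manifest = manifest, out_dir = config$out_dir)
  invisible(out)
}

#' Write the report bundle for one analysis state
#'
#' Renders the direct-effect table (structural paths with intervals and a
#' boolean significance marker), the indirect-effect table (three pathways
#' by two contrasts by group by outcome), the sons-minus-daughters
#' contrasts, and a plain-text summary naming the mediation class of every
#' pathway.
#'
#' @param state list with `fit`, `effects`, `boot` (one entry of
#'   [run_pipeline()]'s states).
#' @param dir output directory.
#' @param suffix file-name suffix (e.g. the bronchodilator state).
#' Alongside the CSVs, a JSON document (`fit-<suffix>.json`, schema
#' version 1) carries the unrounded effects, deltas and fitted coefficients.
#'
#' @return invisibly, the paths written.
#' @export
write_report <- function(state, dir, suffix = "pre") {
  boot <- state$boot
  fn <- function(stem) file.path(dir, paste0(stem, "-", suffix, ".csv"))
  readr::write_csv(boot$paths, fn("direct_effects"))
  indirect <- filter(boot$effects,
                     .data$effect %in% c("nie_m1", "nie_m2", "nie_m1_m2"))
  readr::write_csv(indirect, fn("indirect_effects"))
  readr::write_csv(boot$effects, fn("effects"))
  readr::write_csv(boot$deltas, fn("deltas"))
  jsonlite::write_json(
    list(schema_version = 1L,
         effects = boot$effects, deltas = boot$deltas,
         fit = tidy(state$fit), logLik = glance(state$fit)$logLik,
         converged = glance(state$fit)$converged,
         B = boot$B, n_successful = boot$n_successful),
    file.path(dir, paste0("fit-", suffix, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cls <- boot$effects |>
    filter(.data$effect %in% c("nde", "nie_m1", "nie_m2", "nie_m1_m2")) |>
    tidyr::pivot_wider(id_cols = c("contrast", "group", "outcome"),
                       names_from = "effect",
                       values_from = c("estimate", "significant"))
  lines <- character(0)
  for (i in seq_len(nrow(cls))) {
    row <- cls[i, ]
    for (via in c("nie_m1", "nie_m2", "nie_m1_m2")) {
      est <- row[[paste0("estimate_", via)]]
      sig <- row[[paste0("significant_", via)]]
      k <- classify_mediation(row$significant_nde, sig,
                              sign(est) == sign(row$estimate_nde) |
                                row$estimate_nde == 0)
      lines <- c(lines, sprintf(
        "%s | %s | %s | %s: %s (direct %.0f%s, indirect %.0f%s)",
        row$contrast, row$group, row$outcome, via, as.character(k),
        round_half_away(row$estimate_nde),
        if (row$significant_nde) "*" else "",
        round_half_away(est), if (sig) "*" else ""))
    }
  }
  txt <- file.path(dir, paste0("mediation_classes-", suffix, ".txt"))
  writeLines(lines, txt)
  invisible(c(fn("direct_effects"), fn("indirect_effects"), fn("effects"),
              fn("deltas"), txt))
}
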