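#' Define an unmeasured-confounder sensitivity scenario
#'
#' The sensitivity simulation works in a deliberately simplified
#' single-exposure, single-mediator, single-outcome framework: one or two
#' unmeasured confounders U ~ N(0, 0.001) act on the exposure, the mediator
#' and the outcome with equal strength `beta_u`, and the analysis is run
#' with and without the U's as covariates. Outcomes are on the decilitre
#' scale in this module. Base coefficients default to the published
#' paternal-line sons' FVC pathway (exposure to height to FVC); pass a
#' fitted model's values to study other pathways.
#'
#' @param n_subjects subjects per simulated dataset.
#' @param n_sim simulation runs per scenario.
#' @param n_draws Monte-Carlo draws for each fit's interval.
#' @param n_confounders 1 or 2.
#' @param u_var variance of each confounder.
#' @param beta_u common effect of each confounder on exposure, mediator and
#'   outcome (grid values 0, 1, 3, 5, 7, 9).
#' @param p_exposure marginal exposure prevalence.
#' @param a_em exposure effect on the mediator (cm).
#' @param b_mo mediator effect on the outcome (dL per cm).
#' @param c_eo direct exposure effect on the outcome (dL).
#' @param mediator_sd residual sd of the mediator (cm).
#' @param link exposure-generation link, `"probit"` (default) or `"logit"`.
#' @param seed integer seed.
#' @return object of class `sensitivity_scenario`.
#' @export
sensitivity_scenario <- function(n_subjects = 420L, n_sim = 1000L,
                                 n_draws = 1000L, n_confounders = 1L,
                                 u_var = 0.001, beta_u = 0,
                                 p_exposure = 0.12, a_em = -3.42,
                                 b_mo = 0.61, c_eo = -2.62,
                                 mediator_sd = 6.4,
                                 link = c("probit", "logit"), seed = 1L) {
  link <- match.arg(link)
  if (!n_confounders %in% 1:2) abort("n_confounders must be 1 or 2")
  if (u_var < 0) abort("u_var must be non-negative")
  structure(
    list(n_subjects = check_scalar_count(n_subjects, "n_subjects"),
         n_sim = check_scalar_count(n_sim, "n_sim"),
         n_draws = check_scalar_count(n_draws, "n_draws"),
         n_confounders = as.integer(n_confounders), u_var = u_var,
         beta_u = beta_u, p_exposure = p_exposure, a_em = a_em,
         b_mo = b_mo, c_eo = c_eo, mediator_sd = mediator_sd,
         link = link, seed = as.integer(seed)),
    class = "sensitivity_scenario"
  )
}

#' Simulate one framework dataset
#'
#' Per subject: the confounders are drawn, the binary exposure follows the
#' configured link of (intercept + sum of confounder effects), the mediator
#' is linear in exposure and confounders, and the outcome (decilitres) is
#' linear in exposure, mediator and confounders with unit-variance noise.
#' Deterministic in (scenario seed, run index).
#'
#' @param scenario [sensitivity_scenario()].
#' @param run_index 1-based simulation run.
#' @return tibble with columns `e`, `m`, `o` and `u1` (and `u2`).
#' @export
simulate_framework_dataset <- function(scenario, run_index = 1L) {
  s <- scenario
  run_seed <- (s$seed + 104729 * as.integer(run_index)) %% 2147483647
  with_seed_local(run_seed, {
    n <- s$n_subjects
    U <- matrix(rnorm(n * s$n_confounders, 0, sqrt(s$u_var)),
                n, s$n_confounders)
    icpt <- if (s$link == "probit") qnorm(s$p_exposure) else
      qlogis(s$p_exposure)
    lin <- icpt + rowSums(U) * s$beta_u
    p <- if (s$link == "probit") pnorm(lin) else plogis(lin)
    e <- as.numeric(runif(n) < p)
    m <- s$a_em * e + rowSums(U) * s$beta_u + rnorm(n, 0, s$mediator_sd)
    o <- s$c_eo * e + s$b_mo * m + rowSums(U) * s$beta_u + rnorm(n)
    out <- tibble(e = e, m = m, o = o, u1 = U[, 1])
    if (s$n_confounders == 2) out$u2 <- U[, 2]
    out
  })
}

#' Fit the single-mediator mediation model
#'
#' Product-of-coefficients mediation fit: a mediator regression, an outcome
#' regression and (for completeness) an exposure model, with or without the
#' simulated confounders as covariates. The natural indirect effect is the
#' product of the exposure-to-mediator and mediator-to-outcome
#' coefficients; the direct effect is the outcome model's exposure
#' coefficient. Intervals come from `n_draws` Monte-Carlo draws of the
#' coefficient sampling distributions.
#'
#' @param data tibble from [simulate_framework_dataset()].
#' @param include_u adjust for the confounder columns.
#' @param n_draws Monte-Carlo draws for the intervals.
#' @param seed integer seed for the draws.
#' @return tibble with one row per effect (`nde`, `nie`): estimate, lower,
#'   upper, significant.
#' @export
fit_framework <- function(data, include_u = FALSE, n_draws = 1000L,
                          seed = 1L) {
  if (length(unique(data$e)) < 2)
    abort("degenerate exposure", class = "serimed_degenerate_run")
  ucols <- grep("^u[0-9]$", names(data), value = TRUE)
  rhs_u <- if (include_u && length(ucols))
    paste("+", paste(ucols, collapse = " + ")) else ""
  fm <- lm(stats::as.formula(paste("m ~ e", rhs_u)), data = data)
  fo <- lm(stats::as.formula(paste("o ~ e + m", rhs_u)), data = data)
  fe <- suppressWarnings(
    glm(stats::as.formula(paste("e ~ 1", if (rhs_u == "") "" else rhs_u)),
        family = binomial("probit"), data = data))
  a_hat <- coef(fm)[["e"]]
  b_hat <- coef(fo)[["m"]]
  c_hat <- coef(fo)[["e"]]
  safe_vcov <- function(fit) {
    v <- suppressWarnings(vcov(fit))
    v[!is.finite(v)] <- 0  # degenerate (noiseless) fits have zero variance
    v
  }
  with_seed_local(seed, {
    dm <- mvtnorm::rmvnorm(n_draws, coef(fm), safe_vcov(fm))
    do <- mvtnorm::rmvnorm(n_draws, coef(fo), safe_vcov(fo))
    nie_draws <- dm[, "e"] * do[, "m"]
    nde_draws <- do[, "e"]
    ci_nie <- percentile_ci(nie_draws)
    ci_nde <- percentile_ci(nde_draws)
    tibble(
      effect = c("nde", "nie"),
      estimate = c(c_hat, a_hat * b_hat),
      lower = c(ci_nde[1], ci_nie[1]),
      upper = c(ci_nde[2], ci_nie[2]),
      significant = c(!(ci_nde[1] <= 0 & ci_nde[2] >= 0),
                      !(ci_nie[1] <= 0 & ci_nie[2] >= 0)),
      exposure_model_intercept = coef(fe)[[1]]
    )
  })
}

#' Run one sensitivity scenario
#'
#' Loops the simulation runs, fits the mediation model with and without the
#' unmeasured confounders, and aggregates (i) the proportion of runs where
#' the two analyses reach the same significance conclusion for both the
#' direct and the indirect effect ("results matched") and (ii) the absolute
#' difference of the average direct and indirect estimates between the two
#' analyses. Runs with a degenerate exposure are skipped and counted; more
#' than 5% skipped is an error.
#'
#' @param scenario [sensitivity_scenario()].
#' @param keep_runs keep the per-run estimates in the result.
#' @return one-row tibble (class `sensitivity_result`): scenario metadata,
#'   `match_proportion`, `avg_abs_diff_nde`, `avg_abs_diff_nie`,
#'   `avg_abs_diff` (mean of the two), `n_skipped`.
#' @export
run_scenario <- function(scenario, keep_runs = FALSE) {
  s <- scenario
  runs <- vector("list", s$n_sim)
  skipped <- 0L
  for (r in seq_len(s$n_sim)) {
    dat <- simulate_framework_dataset(s, r)
    fit_seed <- (s$seed + 7919 * r) %% 2147483647
    with_u <- tryCatch(
      fit_framework(dat, include_u = TRUE, n_draws = s$n_draws,
                    seed = fit_seed),
      serimed_degenerate_run = function(e) NULL)
    if (is.null(with_u)) { skipped <- skipped + 1L; next }
    without_u <- fit_framework(dat, include_u = FALSE, n_draws = s$n_draws,
                               seed = fit_seed)
    runs[[r]] <- tibble(
      run = r,
      nde_with = with_u$estimate[1], nie_with = with_u$estimate[2],
      nde_without = without_u$estimate[1],
      nie_without = without_u$estimate[2],
      match = with_u$significant[1] == without_u$significant[1] &
        with_u$significant[2] == without_u$significant[2]
    )
  }
  if (skipped > 0.05 * s$n_sim)
    abort(sprintf("%d of %d runs skipped (degenerate exposure)",
                  skipped, s$n_sim))
  runs <- bind_rows(runs)
  d_nde <- abs(mean(runs$nde_with) - mean(runs$nde_without))
  d_nie <- abs(mean(runs$nie_with) - mean(runs$nie_without))
  out <- tibble(
    n_confounders = s$n_confounders, beta_u = s$beta_u, u_var = s$u_var,
    n_subjects = s$n_subjects, n_sim = s$n_sim - skipped,
    match_proportion = mean(runs$match),
    avg_abs_diff_nde = d_nde, avg_abs_diff_nie = d_nie,
    avg_abs_diff = (d_nde + d_nie) / 2,
    n_skipped = skipped
  )
  if (keep_runs) attr(out, "runs") <- runs
  class(out) <- c("sensitivity_result", class(out))
  out
}

#' Run a sensitivity grid
#'
#' One [run_scenario()] per combination of confounder-strength grid value
#' and number of confounders, with seeds offset so scenarios are independent
#' yet reproducible.
#'
#' @param scenario base [sensitivity_scenario()].
#' @param beta_grid confounder strengths (default the 0/1/3/5/7/9 grid).
#' @param n_confounders vector over 1 and/or 2 confounders.
#' @return tibble of one result row per scenario.
#' @export
run_grid <- function(scenario, beta_grid = c(0, 1, 3, 5, 7, 9),
                     n_confounders = c(1L, 2L)) {
  combos <- expand.grid(beta_u = beta_grid, n_confounders = n_confounders)
  bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    s <- scenario
    s$beta_u <- combos$beta_u[i]
    s$n_confounders <- as.integer(combos$n_confounders[i])
    s$seed <- (scenario$seed + 15485863 * i) %% 2147483647
    run_scenario(s)
  }))
}
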