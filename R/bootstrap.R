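#' Resample parent clusters
#'
#' Draws parents with replacement up to the original parent count; each
#' drawn parent contributes all of their offspring. Parents drawn more than
#' once receive distinct synthetic cluster ids so downstream code never
#' merges duplicated families.
#'
#' @param data cohort tibble (one line).
#' @param seed integer seed.
#' @return resampled cohort tibble.
#' @export
resample_clusters <- function(data, seed = 1L) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("empty cohort")
  parents <- unique(data$parent_id)
  with_seed_local(seed, {
    picks <- sample(parents, length(parents), replace = TRUE)
    rows_of <- split(seq_len(nrow(data)), data$parent_id)
    idx <- unlist(rows_of[picks], use.names = FALSE)
    out <- data[idx, ]
    reps <- rep(seq_along(picks),
                vapply(rows_of[picks], length, 0L))
    out$parent_id <- paste0(out$parent_id, "::", reps)
    out$offspring_id <- paste0(out$offspring_id, "::", reps)
    out
  })
}

#' Percentile confidence interval
#'
#' Empirical-quantile endpoints of a bootstrap sample using linear
#' interpolation between order statistics ([stats::quantile()] type 7); no
#' bias correction or acceleration.
#'
#' @param values numeric vector of bootstrap replicates.
#' @param level percentile pair, default `c(2.5, 97.5)`.
#' @return named numeric `c(lower, upper)`.
#' @export
#' @examples
#' percentile_ci(1:100)  # 3.475, 97.525
percentile_ci <- function(values, level = c(2.5, 97.5)) {
  if (!length(values)) abort("empty bootstrap sample")
  if (length(level) != 2 || any(level <= 0 | level >= 100) ||
      abs(sum(level) - 100) > 1e-8)
    abort("`level` must be a symmetric percentile pair inside (0, 100)")
  q <- quantile(values, probs = sort(level) / 100, type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Cluster bootstrap of all mediation effects
#'
#' Refits the multi-group model on `B` cluster resamples (parents drawn with
#' replacement within the line; sex groups re-formed per resample) and
#' returns non-bias-corrected percentile confidence intervals for every
#' natural effect, every structural path, and every sons-minus-daughters
#' difference. Group-difference intervals are percentiles of the
#' per-resample difference. Refits that fail to converge are dropped and
#' counted; the run errors if fewer than `min_success` of resamples
#' succeed.
#'
#' @param data cohort tibble.
#' @param spec [model_spec()].
#' @param B number of resamples (10,000 in the shipped pipeline
#'   configuration; smaller values are appropriate interactively).
#' @param seed integer seed; (seed, B, data) fully determine the intervals.
#' @param level percentile pair for [percentile_ci()].
#' @param min_success minimum fraction of converged refits.
#' @param fit optional pre-computed [fit_mediation()] full-sample fit.
#' @param keep_draws retain the per-resample parameter draws (see
#'   [bootstrap_coef_draws()]).
#' @param control optimiser control for the refits.
#' @return object of class `serimed_boot`: tibbles `effects` (per contrast,
#'   group, outcome and effect: estimate, lower, upper, significant),
#'   `deltas` (sons minus daughters), `paths` (structural coefficients),
#'   and metadata (`B`, `n_successful`, `seed`).
#' @export
bootstrap_effects <- function(data, spec = model_spec(), B = 500L,
                              seed = 1L, level = c(2.5, 97.5),
                              min_success = 0.95, fit = NULL,
                              keep_draws = FALSE, control = list()) {
  B <- check_scalar_count(B, "B")
  fit <- fit %||% fit_mediation(data, spec, control = control)
  if (!all(vapply(fit$groups, `[[`, TRUE, "converged")))
    abort("full-sample fit did not converge; bootstrap not started")
  frame <- fit$frame
  scaling <- fit$scaling
  ctl <- modifyList(default_control(), control)
  K <- frame$K
  sframe <- scale_frame(frame, scaling)
  res <- with_seed_local(seed, {
    .cpp_bootstrap(B, K, sframe$X4, sframe$X6, sframe$m1, sframe$W,
                   frame$cluster, frame$group, max(frame$cluster),
                   fit$groups$son$theta_scaled,
                   fit$groups$daughter$theta_scaled,
                   fit$groups$son$hessian_inv,
                   fit$groups$daughter$hessian_inv,
                   ctl$maxit, ctl$tol_ll, ctl$tol_grad)
  })
  ok <- res$conv1 & res$conv2
  n_ok <- sum(ok)
  if (n_ok < min_success * B)
    abort(sprintf(
      "only %d of %d bootstrap refits converged (threshold %.0f%%)",
      n_ok, B, 100 * min_success))
  if (n_ok < B)
    inform(sprintf("dropped %d non-converged bootstrap refits", B - n_ok))

  draws <- list(son = res$draws1[ok, , drop = FALSE],
                daughter = res$draws2[ok, , drop = FALSE])
  eff_draws <- lapply(draws, function(m)
    effect_draws_from_theta(m, K, scaling, frame$outcome_names))
  path_draws <- lapply(draws, function(m)
    path_draws_from_theta(m, K, scaling, frame$outcome_names))

  point <- decompose_effects(fit)
  effects <- bind_rows(lapply(SEX_LEVELS, function(g) {
    m <- eff_draws[[g]]
    est <- filter(point, .data$group == g)
    est <- est[match(colnames(m), effect_key(est)), ]
    cis <- apply(m, 2, percentile_ci, level = level)
    mutate(est, lower = cis[1, ], upper = cis[2, ],
           significant = !(cis[1, ] <= 0 & cis[2, ] >= 0))
  }))

  delta_m <- eff_draws$son - eff_draws$daughter
  delta_pt <- group_difference(point)
  key <- paste(delta_pt$contrast, delta_pt$outcome, delta_pt$effect, sep = ".")
  delta_m <- delta_m[, match(key, colnames(delta_m)), drop = FALSE]
  dcis <- apply(delta_m, 2, percentile_ci, level = level)
  deltas <- mutate(delta_pt, estimate = .data$delta, .keep = "unused") |>
    mutate(lower = dcis[1, ], upper = dcis[2, ],
           significant = !(dcis[1, ] <= 0 & dcis[2, ] >= 0))

  tidy_fit <- tidy(fit)
  paths <- bind_rows(lapply(SEX_LEVELS, function(g) {
    m <- path_draws[[g]]
    cis <- apply(m, 2, percentile_ci, level = level)
    info <- strsplit(colnames(m), ".", fixed = TRUE)
    tb <- tibble(
      group = g,
      equation = vapply(info, `[[`, "", 1),
      term = vapply(info, `[[`, "", 2),
      lower = cis[1, ], upper = cis[2, ])
    left_join(tb, tidy_fit, by = c("group", "equation", "term")) |>
      mutate(significant = !(.data$lower <= 0 & .data$upper >= 0)) |>
      select("group", "equation", "term", "estimate", "lower", "upper",
             "significant")
  }))

  out <- structure(
    list(effects = effects, deltas = deltas, paths = paths,
         B = B, n_successful = n_ok, seed = seed, level = sort(level),
         spec = spec, fit = fit),
    class = "serimed_boot"
  )
  if (keep_draws) {
    out$draws <- draws
    out$scaling <- scaling
    out$outcome_names <- frame$outcome_names
    out$K <- K
  }
  out
}

#' Structural-coefficient bootstrap draws
#'
#' Converts the retained per-resample parameter draws of a
#' [bootstrap_effects()] run (`keep_draws = TRUE`) back to the structural
#' scale: one row per successful resample, one column per coefficient
#' (named `equation.term`), plus `sigma_height`.
#'
#' @param boot a `serimed_boot` object with retained draws.
#' @param group `"son"` or `"daughter"`.
#' @return tibble of coefficient draws.
#' @export
bootstrap_coef_draws <- function(boot, group = "son") {
  if (is.null(boot$draws)) abort("bootstrap was run without keep_draws")
  group <- match.arg(group, SEX_LEVELS)
  m <- boot$draws[[group]]
  rows <- lapply(seq_len(nrow(m)), function(b) {
    th <- theta_scale(m[b, ], boot$K, boot$scaling, invert = TRUE)
    cf <- theta_to_structural(th, boot$outcome_names)
    vals <- c(
      setNames(cf$mediator, paste0("m1_latent.", names(cf$mediator))),
      setNames(cf$height, paste0("height_cm.", names(cf$height))),
      unlist(lapply(names(cf$outcomes), function(oc)
        setNames(cf$outcomes[[oc]], paste0(oc, ".",
                                           names(cf$outcomes[[oc]]))))),
      sigma_height = cf$sigma_height
    )
    as_tibble(as.list(vals))
  })
  bind_rows(rows)
}

effect_key <- function(tb) paste(tb$contrast, tb$outcome, tb$effect, sep = ".")

# vectorised over bootstrap draws: reduced-form scaled thetas -> the natural
# effect scale, without building per-draw coefficient objects
structural_cols <- function(m, K, s) {
  cols <- list()
  a1 <- m[, 2]; a2 <- m[, 3]
  d <- m[, 4 + 4 + 6 * K + 1] * s$m_sd
  pi_e <- function(base, j, sdv) m[, base + j - 1] * sdv
  h1 <- pi_e(5, 2, s$m_sd) - d * a1
  h2 <- pi_e(5, 3, s$m_sd) - d * a2
  b1 <- b2 <- c1 <- c2 <- list()
  for (k in seq_len(K)) {
    base <- 8 + 6 * (k - 1) + 1
    off <- 4 + 4 + 6 * K + 1
    b1k <- m[, off + k] * s$y_sd[k]
    b2k <- m[, off + K + k] * s$y_sd[k] / s$m_sd
    lam <- b1k + b2k * d
    c1[[k]] <- pi_e(base, 2, s$y_sd[k]) - lam * a1 - b2k * h1
    c2[[k]] <- pi_e(base, 3, s$y_sd[k]) - lam * a2 - b2k * h2
    b1[[k]] <- b1k; b2[[k]] <- b2k
  }
  list(a1 = a1, a2 = a2, h1 = h1, h2 = h2, d = d,
       b1 = b1, b2 = b2, c1 = c1, c2 = c2)
}

effect_draws_from_theta <- function(m, K, scaling, onames) {
  sc <- structural_cols(m, K, scaling)
  out <- list()
  for (ct in c(1, 2)) {
    a <- if (ct == 1) sc$a1 else sc$a2
    h <- if (ct == 1) sc$h1 else sc$h2
    for (k in seq_len(K)) {
      cc <- if (ct == 1) sc$c1[[k]] else sc$c2[[k]]
      nde <- cc
      nie_m1 <- a * sc$b1[[k]]
      nie_m2 <- h * sc$b2[[k]]
      nie_m1_m2 <- a * sc$d * sc$b2[[k]]
      vals <- cbind(nde, nie_m1, nie_m2, nie_m1_m2,
                    nde + nie_m1 + nie_m2 + nie_m1_m2)
      colnames(vals) <- paste(CONTRASTS[ct], onames[k], EFFECT_NAMES,
                              sep = ".")
      out[[length(out) + 1]] <- vals
    }
  }
  do.call(cbind, out)
}

path_draws_from_theta <- function(m, K, scaling, onames) {
  sc <- structural_cols(m, K, scaling)
  out <- cbind(
    "m1_latent.before_puberty" = sc$a1,
    "m1_latent.at30_not_before" = sc$a2,
    "height_cm.before_puberty" = sc$h1,
    "height_cm.at30_not_before" = sc$h2,
    "height_cm.m1_latent" = sc$d
  )
  for (k in seq_len(K)) {
    add <- cbind(sc$c1[[k]], sc$c2[[k]], sc$b1[[k]], sc$b2[[k]])
    colnames(add) <- paste(onames[k],
                           c("before_puberty", "at30_not_before",
                             "m1_latent", "height_cm"), sep = ".")
    out <- cbind(out, add)
  }
  out
}

#' Significance flags of a bootstrap summary
#'
#' An effect is significant when its percentile interval excludes zero;
#' intervals touching zero (inclusive boundary) are not significant.
#'
#' @param summary a `serimed_boot` object or a tibble with `lower`/`upper`.
#' @return logical vector, one flag per interval.
#' @export
significance_flags <- function(summary) {
  if (inherits(summary, "serimed_boot")) summary <- summary$effects
  !(summary$lower <= 0 & summary$upper >= 0)
}

#' @export
print.serimed_boot <- function(x, ...) {
  cat(sprintf("<serimed_boot> B=%d (%d successful), level %.1f/%.1f\n",
              x$B, x$n_successful, x$level[1], x$level[2]))
  print(x$effects, n = 10)
  invisible(x)
}

#' @rdname serimed_tidiers
#' @export
tidy.serimed_boot <- function(x, ...) x$effects

#' @rdname serimed_tidiers
#' @export
glance.serimed_boot <- function(x, ...) {
  tibble(B = x$B, n_successful = x$n_successful, seed = x$seed,
         level_lower = x$level[1], level_upper = x$level[2])
}
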