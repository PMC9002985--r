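# run code under a local RNG state so generators are pure in (params, seed)
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default generator parameters for a line
#'
#' Returns a fully calibrated parameter set for the synthetic two-generation
#' cohort generator. Exposure-category, education and smoking prevalences,
#' offspring-sex probability, age ranges, and group means/sd of height, FEV1
#' and FVC follow the descriptive characteristics of the cohort the model
#' was designed for; structural path coefficients follow the published
#' per-group point estimates; covariate coefficients that are never printed
#' (education, age, smoking effects) use documented physiological defaults.
#' Intercepts and residual scales are solved so that the implied marginal
#' means, prevalences and standard deviations hit the targets exactly under
#' the generative model.
#'
#' @param line `"paternal"` or `"maternal"`.
#' @return object of class `serimed_params`.
#' @export
default_generator_params <- function(line = c("paternal", "maternal")) {
  line <- match.arg(line)
  if (line == "paternal") {
    marginals <- list(
      exposure_probs = c(before_puberty = 0.120, at30_not_before = 0.104,
                         never = 0.776),
      p_edu_low = 0.084,
      p_daughter = 0.531,
      p_smoker = c(son = 0.284, daughter = 0.224),
      age_range = c(18, 51),
      targets = list(
        son = list(p_m1 = 0.127, height = c(181, 6.5),
                   fev1 = c(4387, 629), fvc = c(5490, 727),
                   post_shift = c(fev1 = 144, fvc = -30)),
        daughter = list(p_m1 = 0.296, height = c(168, 6.3),
                        fev1 = c(3277, 405), fvc = c(3987, 492),
                        post_shift = c(fev1 = 82, fvc = -33))
      )
    )
    paths <- list(
      son = list(a = c(0.56, 0.07), h = c(-3.42, -0.17), d = 0.37,
                 fev1 = c(c1 = -164, c2 = -15, b1 = 36, b2 = 42),
                 fvc = c(c1 = -262, c2 = -43, b1 = 54, b2 = 61),
                 theta_age = c(fev1 = -28, fvc = -25)),
      daughter = list(a = c(0.83, -0.02), h = c(-2.11, -0.2), d = -1.17,
                      fev1 = c(c1 = 26, c2 = 51, b1 = 32, b2 = 30),
                      fvc = c(c1 = 78, c2 = 64, b1 = 48, b2 = 41),
                      theta_age = c(fev1 = -22, fvc = -20))
    )
  } else {
    marginals <- list(
      exposure_probs = c(before_puberty = 0.250, at30_not_before = 0.229,
                         never = 0.521),
      p_edu_low = 0.101,
      p_daughter = 0.545,
      p_smoker = c(son = 0.302, daughter = 0.345),
      age_range = c(18, 54),
      targets = list(
        son = list(p_m1 = 0.177, height = c(181, 6.4),
                   fev1 = c(4430, 620), fvc = c(5537, 761),
                   post_shift = c(fev1 = 147, fvc = -11)),
        daughter = list(p_m1 = 0.227, height = c(168, 6.6),
                        fev1 = c(3238, 500), fvc = c(3957, 568),
                        post_shift = c(fev1 = 101, fvc = -15))
      )
    )
    paths <- list(
      son = list(a = c(0.59, 0.54), h = c(0.1, 1.41), d = 1.38,
                 fev1 = c(c1 = 115, c2 = 98, b1 = 114, b2 = 53),
                 fvc = c(c1 = 124, c2 = 116, b1 = 35, b2 = 75),
                 theta_age = c(fev1 = -28, fvc = -25)),
      daughter = list(a = c(0.52, 0.3), h = c(-0.12, 1.1), d = 0.57,
                      fev1 = c(c1 = 160, c2 = 186, b1 = 82, b2 = 42),
                      fvc = c(c1 = 110, c2 = 180, b1 = 83, b2 = 53),
                      theta_age = c(fev1 = -22, fvc = -20))
    )
  }
  covariate_defaults <- list(
    g1 = 0.15,                       # education -> latent overweight (probit)
    g2 = -1.0,                       # education -> height (cm)
    theta_edu = c(fev1 = -40, fvc = -40),
    theta_smk = c(fev1 = -120, fvc = -60),
    outcome_residual_cor = 0.7
  )
  generator_params(line = line, marginals = marginals, paths = paths,
                   covariates = covariate_defaults,
                   offspring_dist = c(`1` = 0.70, `2` = 0.25, `3` = 0.05))
}

#' Build generator parameters
#'
#' Lower-level constructor used by [default_generator_params()]; solves the
#' structural intercepts and residual scales from the target marginals and
#' returns a validated parameter object with one [path_coefs()] per group.
#'
#' @param line line label.
#' @param marginals list of category probabilities, age range and per-group
#'   target moments (see [default_generator_params()]).
#' @param paths per-group structural exposure/mediator paths.
#' @param covariates unprinted covariate coefficients and the outcome
#'   residual correlation.
#' @param offspring_dist named probabilities for 1, 2 or 3 offspring per
#'   parent.
#' @return object of class `serimed_params`.
#' @export
generator_params <- function(line, marginals, paths, covariates,
                             offspring_dist = c(`1` = 0.70, `2` = 0.25,
                                                `3` = 0.05)) {
  probs <- marginals$exposure_probs
  if (abs(sum(probs) - 1) > 1e-8) abort("exposure probabilities must sum to 1")
  if (any(probs < 0) || any(offspring_dist < 0))
    abort("probabilities must be non-negative")
  if (abs(sum(offspring_dist) - 1) > 1e-8)
    abort("offspring_dist probabilities must sum to 1")
  coefficients <- list()
  for (g in SEX_LEVELS)
    coefficients[[g]] <- solve_group_coefs(g, marginals, paths[[g]], covariates)
  structure(
    list(line = line, marginals = marginals, paths = paths,
         covariates = covariates, offspring_dist = offspring_dist,
         coefficients = coefficients),
    class = "serimed_params"
  )
}

#' @export
print.serimed_params <- function(x, ...) {
  cat(sprintf("<serimed_params> line=%s, exposure probs: %s\n", x$line,
              paste(sprintf("%.3f", x$marginals$exposure_probs),
                    collapse = "/")))
  invisible(x)
}

# moments of the group covariate distribution implied by the parameters
covariate_moments <- function(marginals, group) {
  p1 <- marginals$exposure_probs[["before_puberty"]]
  p2 <- marginals$exposure_probs[["at30_not_before"]]
  pe <- marginals$p_edu_low
  ps <- marginals$p_smoker[[group]]
  lo <- marginals$age_range[1]; hi <- marginals$age_range[2]
  list(p1 = p1, p2 = p2, pe = pe, ps = ps,
       age_mu = (lo + hi) / 2, age_var = (hi - lo)^2 / 12)
}

var_exposure <- function(q1, q2, p1, p2) {
  q1^2 * p1 + q2^2 * p2 - (q1 * p1 + q2 * p2)^2
}

# solve intercepts and residual scales so that the implied group marginals
# hit the targets exactly; errors if a target sd is not reachable
solve_group_coefs <- function(group, marginals, gpaths, cov) {
  mom <- covariate_moments(marginals, group)
  tg <- marginals$targets[[group]]
  a1 <- gpaths$a[1]; a2 <- gpaths$a[2]; g1 <- cov$g1
  # P(M1 = 1) = E_x Phi(a0 + a1 E1 + a2 E2 + g1 edu)
  cells <- expand.grid(e = 0:2, u = 0:1)
  cellp <- with(mom, c(1 - p1 - p2, p1, p2)[cells$e + 1] *
                  ifelse(cells$u == 1, pe, 1 - pe))
  lin <- a1 * (cells$e == 1) + a2 * (cells$e == 2) + g1 * cells$u
  a0 <- uniroot(function(a0) sum(cellp * pnorm(a0 + lin)) - tg$p_m1,
                c(-8, 8), tol = 1e-12)$root
  eta_mean <- a0 + a1 * mom$p1 + a2 * mom$p2 + g1 * mom$pe

  h1 <- gpaths$h[1]; h2 <- gpaths$h[2]; d <- gpaths$d; g2 <- cov$g2
  h0 <- tg$height[1] -
    (h1 * mom$p1 + h2 * mom$p2 + g2 * mom$pe + d * eta_mean)
  vx_height <- var_exposure(h1 + d * a1, h2 + d * a2, mom$p1, mom$p2) +
    (g2 + d * g1)^2 * mom$pe * (1 - mom$pe)
  s2h <- tg$height[2]^2 - vx_height - d^2
  if (s2h <= 0)
    abort(sprintf("height target sd unreachable for %s", group))
  sigma_height <- sqrt(s2h)

  outs <- c("fev1", "fvc")
  resid_sd <- numeric(2)
  out_coefs <- list()
  for (k in seq_along(outs)) {
    nm <- outs[k]
    ob <- gpaths[[nm]]
    b1 <- ob[["b1"]]; b2 <- ob[["b2"]]
    th_a <- gpaths$theta_age[[nm]]
    th_e <- cov$theta_edu[[nm]]; th_s <- cov$theta_smk[[nm]]
    lam <- b1 + b2 * d
    m2_mean <- tg$height[1]
    c0 <- tg[[nm]][1] -
      (ob[["c1"]] * mom$p1 + ob[["c2"]] * mom$p2 + th_e * mom$pe +
         th_a * mom$age_mu + th_s * mom$ps + b1 * eta_mean + b2 * m2_mean)
    q1 <- ob[["c1"]] + lam * a1 + b2 * h1
    q2 <- ob[["c2"]] + lam * a2 + b2 * h2
    qe <- th_e + lam * g1 + b2 * g2
    vx <- var_exposure(q1, q2, mom$p1, mom$p2) +
      qe^2 * mom$pe * (1 - mom$pe) +
      th_a^2 * mom$age_var + th_s^2 * mom$ps * (1 - mom$ps)
    v_res <- tg[[nm]][2]^2 - vx - lam^2 - b2^2 * sigma_height^2
    if (v_res <= 0)
      abort(sprintf("%s target sd unreachable for %s", nm, group))
    resid_sd[k] <- sqrt(v_res)
    out_coefs[[nm]] <- setNames(
      c(c0, ob[["c1"]], ob[["c2"]], th_e, th_a, th_s, b1, b2),
      c(X6_TERMS, "m1_latent", "height_cm"))
  }
  rho <- cov$outcome_residual_cor
  Sig <- diag(resid_sd) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(resid_sd)
  dimnames(Sig) <- list(outs, outs)
  path_coefs(
    mediator = setNames(c(a0, a1, a2, g1), X4_TERMS),
    height = setNames(c(h0, h1, h2, g2, d), c(X4_TERMS, "m1_latent")),
    outcomes = out_coefs,
    sigma_height = sigma_height,
    sigma_outcomes = Sig
  )
}

#' Generate a synthetic two-generation cohort
#'
#' Samples parents (education, three-level overweight exposure, number of
#' offspring) and their offspring (sex, age, smoking), then generates the
#' latent overweight mediator, adult height, and correlated FEV1/FVC from
#' the exact structural system the estimator assumes, using the parameters'
#' per-group [path_coefs()]. Offspring of the same parent share the
#' parent-level exposure and education; the binary overweight flag equals
#' `m1_star > 0` exactly.
#'
#' @param params [`serimed_params`] object.
#' @param n_parents number of parents (clusters) to draw.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a validated `cohort_tbl` with attributes `oracle` (tibble of
#'   `offspring_id`, `m1_star`), `true_effects` (the generator's implied
#'   effect decomposition, see [decompose_effects()]), `params` and `seed`.
#' @export
generate_cohort <- function(params, n_parents, seed = 1L) {
  if (!inherits(params, "serimed_params")) abort("params must be serimed_params")
  n_parents <- check_scalar_count(n_parents, "n_parents")
  m <- params$marginals
  with_seed_local(seed, {
    exposure <- sample(EXPOSURE_LEVELS, n_parents, replace = TRUE,
                       prob = m$exposure_probs[EXPOSURE_LEVELS])
    edu <- runif(n_parents) < m$p_edu_low
    n_off <- sample(as.integer(names(params$offspring_dist)), n_parents,
                    replace = TRUE, prob = params$offspring_dist)
    parent_id <- sprintf("P%05d", seq_len(n_parents))
    idx <- rep(seq_len(n_parents), n_off)
    n <- length(idx)
    sex <- ifelse(runif(n) < m$p_daughter, "daughter", "son")
    age <- runif(n, m$age_range[1], m$age_range[2])
    smoker <- runif(n) < ifelse(sex == "daughter",
                                m$p_smoker[["daughter"]], m$p_smoker[["son"]])
    e1 <- as.numeric(exposure[idx] == "before_puberty")
    e2 <- as.numeric(exposure[idx] == "at30_not_before")
    eduo <- as.numeric(edu[idx])

    m1_star <- height <- fev1 <- fvc <- numeric(n)
    eps1 <- rnorm(n)
    eps2 <- rnorm(n)
    Z <- matrix(rnorm(2 * n), n, 2)
    for (g in SEX_LEVELS) {
      gi <- sex == g
      if (!any(gi)) next
      cf <- params$coefficients[[g]]
      a <- cf$mediator; h <- cf$height
      eta <- a[["intercept"]] + a[["before_puberty"]] * e1[gi] +
        a[["at30_not_before"]] * e2[gi] + a[["parent_edu_low"]] * eduo[gi]
      ms <- eta + eps1[gi]
      m1_star[gi] <- ms
      ht <- h[["intercept"]] + h[["before_puberty"]] * e1[gi] +
        h[["at30_not_before"]] * e2[gi] + h[["parent_edu_low"]] * eduo[gi] +
        h[["m1_latent"]] * ms + cf$sigma_height * eps2[gi]
      height[gi] <- ht
      Lg <- t(chol(cf$sigma_outcomes))
      E <- Z[gi, , drop = FALSE] %*% t(Lg)
      for (k in 1:2) {
        o <- cf$outcomes[[k]]
        y <- o[["intercept"]] + o[["before_puberty"]] * e1[gi] +
          o[["at30_not_before"]] * e2[gi] +
          o[["parent_edu_low"]] * eduo[gi] + o[["age"]] * age[gi] +
          o[["ever_smoker"]] * as.numeric(smoker[gi]) +
          o[["m1_latent"]] * ms + o[["height_cm"]] * ht + E[, k]
        if (k == 1) fev1[gi] <- y else fvc[gi] <- y
      }
    }
    shift <- function(nm) {
      s <- vapply(sex, function(g) m$targets[[g]]$post_shift[[nm]], 0)
      s + rnorm(n, 0, 50)
    }
    fev1_post <- fev1 + shift("fev1")
    fvc_post <- fvc + shift("fvc")

    off_seq <- unlist(lapply(n_off, seq_len))
    cohort <- tibble(
      offspring_id = paste0(parent_id[idx], "-", off_seq),
      parent_id = parent_id[idx],
      line = params$line,
      sex = sex,
      age = age,
      ever_smoker = smoker,
      m1_overweight_prepuberty = m1_star > 0,
      height_cm = height,
      fev1_ml = fev1,
      fvc_ml = fvc,
      fev1_post_ml = fev1_post,
      fvc_post_ml = fvc_post,
      parent_edu_low = edu[idx],
      parent_exposure = exposure[idx]
    )
    out <- suppressMessages(validate_cohort(cohort))
    if (nrow(out) < n)
      warn(sprintf("%d generated rows failed plausibility screening", n - nrow(out)))
    oracle <- tibble(offspring_id = cohort$offspring_id, m1_star = m1_star)
    attr(out, "oracle") <- oracle[oracle$offspring_id %in% out$offspring_id, ]
    attr(out, "true_effects") <- true_effects(params)
    attr(out, "params") <- params
    attr(out, "seed") <- seed
    attr(out, "provenance") <- paste0("generator:seed=", seed)
    out
  })
}

# generator-implied effect decomposition, by construction of the model
true_effects <- function(params) {
  bind_rows(lapply(SEX_LEVELS, function(g)
    decompose_effects(params$coefficients[[g]], group = g)))
}

#' Attach the latent-mediator oracle column
#'
#' Binds the generator's latent `m1_star` values onto a synthetic cohort so
#' that [oracle_fit()] can treat the latent mediator as observed.
#'
#' @param data cohort generated by [generate_cohort()].
#' @param oracle tibble with `offspring_id` and `m1_star`; defaults to the
#'   cohort's `oracle` attribute.
#' @return the cohort with an `m1_star` column appended.
#' @export
attach_latent_oracle <- function(data, oracle = attr(data, "oracle")) {
  if (is.null(oracle)) abort("no oracle columns available")
  if (!all(data$offspring_id %in% oracle$offspring_id))
    abort("oracle ids do not align with the cohort")
  out <- left_join(as_tibble(data), oracle, by = "offspring_id")
  class(out) <- unique(c("cohort_tbl", class(out)))
  for (a in c("oracle", "true_effects", "params", "seed", "provenance"))
    attr(out, a) <- attr(data, a)
  out
}
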