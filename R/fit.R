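#' Two-stage starting values
#'
#' Computes starting values for the full-information fit: a probit
#' regression of the binary overweight flag on exposure and education for
#' the mediator equation, then least-squares fits in which the latent
#' mediator is replaced by its conditional expectation given the binary flag
#' (the inverse-Mills construction), and residual moments for the scales.
#' Deterministic in the data.
#'
#' @param data cohort tibble.
#' @param spec [model_spec()].
#' @return named list with one [path_coefs()] per group.
#' @export
initial_values <- function(data, spec = model_spec()) {
  frame <- build_model_frame(data, spec)
  out <- list()
  for (g in seq_along(SEX_LEVELS)) {
    rows <- which(frame$group == g)
    if (!length(rows)) abort(paste0("empty group: ", SEX_LEVELS[g]))
    out[[SEX_LEVELS[g]]] <- initial_values_group(frame, rows)
  }
  out
}

initial_values_group <- function(frame, rows) {
  m1 <- frame$m1[rows]
  if (length(unique(m1)) < 2) abort("degenerate mediator")
  X4 <- frame$X4[rows, , drop = FALSE]
  X6 <- frame$X6[rows, , drop = FALSE]
  W <- frame$W[rows, , drop = FALSE]
  pr <- suppressWarnings(
    glm.fit(X4, m1, family = binomial(link = "probit"))
  )
  a <- coef(pr)
  eta <- drop(X4 %*% a)
  # E[M1* | M1, x] for a unit-variance latent residual
  mills <- ifelse(m1 == 1, dnorm(eta) / pnorm(eta),
                  -dnorm(eta) / pnorm(-eta))
  m1s <- eta + mills
  Xh <- cbind(X4, m1s)
  fh <- lm.fit(Xh, W[, 1])
  h <- coef(fh)
  sigma_height <- max(sd(fh$residuals), 1e-6)
  K <- frame$K
  Xo <- cbind(X6, m1s, W[, 1])
  R <- matrix(0, length(rows), K)
  outcomes <- list()
  for (k in seq_len(K)) {
    fo <- lm.fit(Xo, W[, k + 1])
    outcomes[[frame$outcome_names[k]]] <- setNames(
      coef(fo), c(X6_TERMS, "m1_latent", "height_cm"))
    R[, k] <- fo$residuals
  }
  Sig <- crossprod(R) / (length(rows) - 1)
  # guard against a degenerate starting covariance
  if (K == 2) {
    rho <- Sig[1, 2] / sqrt(Sig[1, 1] * Sig[2, 2])
    if (abs(rho) > 0.98) Sig[1, 2] <- Sig[2, 1] <- 0.98 * sign(rho) *
        sqrt(Sig[1, 1] * Sig[2, 2])
  }
  path_coefs(
    mediator = setNames(a, X4_TERMS),
    height = setNames(h, c(X4_TERMS, "m1_latent")),
    outcomes = outcomes,
    sigma_height = sigma_height,
    sigma_outcomes = Sig
  )
}

default_control <- function() {
  list(maxit = 500L, tol_ll = 1e-9, tol_grad = 1e-6, restarts = 3L,
       jitter_sd = 0.05)
}

#' Fit the structural model for one offspring-sex group
#'
#' Maximises the observed-data likelihood of the latent-probit serial
#' mediation system by full-information maximum likelihood: the latent
#' mediator residual (variance fixed at 1, threshold at 0) is marginalised
#' exactly, leaving a multivariate-normal density for (height, outcomes)
#' times a probit probability for the binary flag. Optimisation is BFGS with
#' analytic gradients on standardised data; on non-convergence the fit is
#' restarted from jittered starting values and the best likelihood wins.
#'
#' @param data cohort tibble.
#' @param spec [model_spec()].
#' @param group `"son"` or `"daughter"`.
#' @param init optional [path_coefs()] starting values.
#' @param control list overriding `maxit`, `tol_ll`, `tol_grad`, `restarts`.
#' @return object of class `serimed_group_fit`: `coefficients`
#'   ([path_coefs()]), `logLik`, `converged`, `iterations`, `n`, `group`.
#' @export
fit_group_model <- function(data, spec = model_spec(), group = "son",
                            init = NULL, control = list()) {
  group <- match.arg(group, SEX_LEVELS)
  frame <- build_model_frame(data, spec)
  scaling <- frame_scaling(frame)
  g <- match(group, SEX_LEVELS)
  rows <- which(frame$group == g)
  if (!length(rows)) abort(paste0("empty group: ", group))
  init <- init %||% initial_values_group(frame, rows)
  fit_group_frame(frame, scaling, rows, init, group, control)
}

fit_group_frame <- function(frame, scaling, rows, init, group,
                            control = list()) {
  ctl <- modifyList(default_control(), control)
  sframe <- scale_frame(frame, scaling)
  theta0 <- theta_scale(structural_to_theta(init), frame$K, scaling)
  run <- function(th) {
    .cpp_fit(th, frame$K, sframe$X4, sframe$X6, sframe$m1, sframe$W,
             rows, ctl$maxit, ctl$tol_ll, ctl$tol_grad)
  }
  fit <- run(theta0)
  tries <- 0
  best <- fit
  while (!best$converged && tries < ctl$restarts) {
    tries <- tries + 1
    jitter <- rnorm(length(theta0), 0, ctl$jitter_sd)
    cand <- run(theta0 + jitter)
    if (cand$value < best$value || (cand$converged && !best$converged))
      best <- cand
  }
  theta_nat <- theta_scale(best$theta, frame$K, scaling, invert = TRUE)
  coefs <- theta_to_structural(theta_nat, frame$outcome_names)
  ll <- -.cpp_negloglik(theta_nat, frame$K, frame$X4, frame$X6, frame$m1,
                        frame$W, rows)
  structure(
    list(coefficients = coefs, logLik = ll, converged = best$converged,
         iterations = best$iter, grad_norm = best$grad_norm,
         n = length(rows), group = group,
         theta_scaled = best$theta, hessian_inv = best$H,
         scaling = scaling),
    class = "serimed_group_fit"
  )
}

#' @export
print.serimed_group_fit <- function(x, ...) {
  cat(sprintf("<serimed_group_fit> group=%s n=%d logLik=%.2f converged=%s\n",
              x$group, x$n, x$logLik, x$converged))
  invisible(x)
}

#' Fit the multi-group mediation model
#'
#' Fits the structural system independently in sons and daughters (the
#' moderator splits the sample; no cross-group equality constraints),
#' retaining the parent-cluster structure for the bootstrap stage.
#'
#' @param data cohort tibble.
#' @param spec [model_spec()].
#' @param control optimiser control, see [fit_group_model()].
#' @return object of class `serimed_fit` with one group fit per sex.
#' @export
fit_mediation <- function(data, spec = model_spec(), control = list()) {
  frame <- build_model_frame(data, spec)
  scaling <- frame_scaling(frame)
  groups <- list()
  for (g in seq_along(SEX_LEVELS)) {
    rows <- which(frame$group == g)
    if (!length(rows)) abort(paste0("empty group: ", SEX_LEVELS[g]))
    init <- withCallingHandlers(
      initial_values_group(frame, rows),
      error = function(e) abort(paste0(SEX_LEVELS[g], ": ", conditionMessage(e)))
    )
    groups[[SEX_LEVELS[g]]] <-
      fit_group_frame(frame, scaling, rows, init, SEX_LEVELS[g], control)
  }
  structure(
    list(groups = groups, spec = spec, frame = frame, scaling = scaling),
    class = "serimed_fit"
  )
}

#' @export
print.serimed_fit <- function(x, ...) {
  cat(sprintf("<serimed_fit> line=%s outcomes=%s\n", x$spec$line,
              x$spec$outcomes))
  for (g in names(x$groups)) print(x$groups[[g]])
  invisible(x)
}

#' Observed-data log-likelihood
#'
#' Evaluates the marginal log-likelihood of one group's data at given
#' structural coefficients. The default `"closed_form"` method uses the
#' exact marginalisation of the latent residual; `"quadrature"` approximates
#' the same integral by fixed-order Gauss-Hermite quadrature over the latent
#' residual, in which the binary flag is the deterministic threshold
#' indicator at each node (deterministic for a fixed order; orders below 11
#' are refused).
#'
#' @param data cohort tibble.
#' @param spec [model_spec()].
#' @param group `"son"` or `"daughter"`.
#' @param coefs [path_coefs()] at which to evaluate.
#' @param method `"closed_form"` or `"quadrature"`.
#' @param gh_order Gauss-Hermite order for the quadrature method.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(data, spec = model_spec(), group = "son",
                            coefs = NULL, method = c("closed_form",
                                                     "quadrature"),
                            gh_order = NULL) {
  method <- match.arg(method)
  group <- match.arg(group, SEX_LEVELS)
  if (is.null(coefs)) abort("`coefs` must be supplied")
  frame <- build_model_frame(data, spec)
  rows <- which(frame$group == match(group, SEX_LEVELS))
  if (!length(rows)) abort(paste0("empty group: ", group))
  if (method == "closed_form") {
    theta <- structural_to_theta(coefs)
    ll <- -.cpp_negloglik(theta, frame$K, frame$X4, frame$X6, frame$m1,
                          frame$W, rows)
    if (!is.finite(ll) || ll <= -1e9)
      abort("non-finite likelihood at the supplied coefficients")
    return(ll)
  }
  gh_order <- gh_order %||% spec$quadrature_order
  if (gh_order < 11) abort("quadrature order below 11 is not allowed")
  quadrature_loglik(frame, rows, coefs, gh_order)
}

quadrature_loglik <- function(frame, rows, coefs, gh_order) {
  gq <- statmod::gauss.quad(gh_order, kind = "hermite")
  nodes <- sqrt(2) * gq$nodes
  wts <- gq$weights / sqrt(pi)
  X4 <- frame$X4[rows, , drop = FALSE]
  X6 <- frame$X6[rows, , drop = FALSE]
  W <- frame$W[rows, , drop = FALSE]
  m1 <- frame$m1[rows]
  K <- frame$K
  a <- unname(coefs$mediator)
  hv <- unname(coefs$height[X4_TERMS]); d <- coefs$height[["m1_latent"]]
  eta <- drop(X4 %*% a)
  nu <- drop(X4 %*% hv)
  kap <- matrix(0, length(rows), K)
  b1 <- b2 <- numeric(K)
  for (k in seq_len(K)) {
    o <- coefs$outcomes[[k]]
    kap[, k] <- drop(X6 %*% unname(o[X6_TERMS]))
    b1[k] <- o[["m1_latent"]]; b2[k] <- o[["height_cm"]]
  }
  Sig <- coefs$sigma_outcomes
  L <- numeric(length(rows))
  for (j in seq_along(nodes)) {
    m1s <- eta + nodes[j]
    ind <- as.numeric((m1s > 0) == (m1 == 1))
    mu2 <- nu + d * m1s
    dens <- dnorm(W[, 1], mu2, coefs$sigma_height)
    # outcomes condition on the realised height, not its mean
    muY <- kap + outer(m1s, b1) + W[, 1] %o% b2
    resY <- W[, -1, drop = FALSE] - muY
    dy <- mvtnorm::dmvnorm(resY, sigma = Sig)
    L <- L + wts[j] * ind * dens * dy
  }
  if (any(L <= 0)) {
    bad <- frame$data$offspring_id[rows[which(L <= 0)[1]]]
    abort(paste0("non-finite quadrature density at row ", bad))
  }
  sum(log(L))
}

#' Oracle fit treating the latent mediator as observed
#'
#' Least-squares/Gaussian fits of the same structural system on a synthetic
#' cohort carrying the generator's latent `m1_star` column (see
#' [attach_latent_oracle()]). Consistent for the same structural parameters
#' as [fit_group_model()] and used as an independent estimator in tests.
#'
#' @param data cohort tibble with an `m1_star` column.
#' @param spec [model_spec()].
#' @param group `"son"` or `"daughter"`.
#' @return [path_coefs()] estimates.
#' @export
oracle_fit <- function(data, spec = model_spec(), group = "son") {
  if (!"m1_star" %in% names(data)) abort("missing oracle column m1_star")
  group <- match.arg(group, SEX_LEVELS)
  frame <- build_model_frame(data, spec)
  rows <- which(frame$group == match(group, SEX_LEVELS))
  if (!length(rows)) abort(paste0("empty group: ", group))
  m1s <- frame$data$m1_star[rows]
  X4 <- frame$X4[rows, , drop = FALSE]
  X6 <- frame$X6[rows, , drop = FALSE]
  W <- frame$W[rows, , drop = FALSE]
  fa <- lm.fit(X4, m1s)
  fh <- lm.fit(cbind(X4, m1s), W[, 1])
  K <- frame$K
  outcomes <- list()
  R <- matrix(0, length(rows), K)
  Xo <- cbind(X6, m1s, W[, 1])
  for (k in seq_len(K)) {
    fo <- lm.fit(Xo, W[, k + 1])
    outcomes[[frame$outcome_names[k]]] <- setNames(
      coef(fo), c(X6_TERMS, "m1_latent", "height_cm"))
    R[, k] <- fo$residuals
  }
  path_coefs(
    mediator = setNames(coef(fa), X4_TERMS),
    height = setNames(coef(fh), c(X4_TERMS, "m1_latent")),
    outcomes = outcomes,
    sigma_height = max(sd(fh$residuals), 1e-12),
    sigma_outcomes = crossprod(R) / (length(rows) - 1) +
      diag(1e-12, K)
  )
}

#' @rdname serimed_tidiers
#' @export
tidy.serimed_fit <- function(x, ...) {
  bind_rows(lapply(names(x$groups), function(g) {
    cf <- x$groups[[g]]$coefficients
    bind_rows(
      tibble(group = g, equation = "m1_latent",
             term = names(cf$mediator), estimate = unname(cf$mediator)),
      tibble(group = g, equation = "height_cm",
             term = names(cf$height), estimate = unname(cf$height)),
      bind_rows(lapply(names(cf$outcomes), function(oc)
        tibble(group = g, equation = oc, term = names(cf$outcomes[[oc]]),
               estimate = unname(cf$outcomes[[oc]]))))
    )
  }))
}

#' Tidiers for fitted serial-mediation objects
#'
#' `tidy()` returns one row per structural coefficient (fit) or per effect
#' with its confidence interval (bootstrap); `glance()` returns one-row
#' model summaries.
#'
#' @param x a `serimed_fit` or `serimed_boot` object.
#' @param ... unused.
#' @name serimed_tidiers
#' @return a tibble.
#' @export
glance.serimed_fit <- function(x, ...) {
  tibble(
    line = x$spec$line,
    outcomes = x$spec$outcomes,
    logLik = sum(vapply(x$groups, `[[`, 0, "logLik")),
    converged = all(vapply(x$groups, `[[`, TRUE, "converged")),
    n = sum(vapply(x$groups, `[[`, 0L, "n")),
    n_groups = length(x$groups)
  )
}
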