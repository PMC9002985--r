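X4_TERMS <- c("intercept", "before_puberty", "at30_not_before", "parent_edu_low")
X6_TERMS <- c(X4_TERMS, "age", "ever_smoker")

#' Structural path coefficients for one group
#'
#' Container for the group-specific structural system: a probit equation for
#' the latent overweight mediator M1* (unit residual variance, threshold at
#' zero), a linear equation for adult height (M2) that loads on the latent
#' M1*, and one linear equation per lung-function outcome loading on both
#' M1* and M2. Residual scales are the height residual sd and the outcome
#' residual covariance.
#'
#' @param mediator named numeric, terms `intercept`, `before_puberty`,
#'   `at30_not_before`, `parent_edu_low` (probit scale).
#' @param height named numeric, the same four terms plus `m1_latent` (cm per
#'   latent-sd unit).
#' @param outcomes named list of named numerics (one per outcome, e.g.
#'   `fev1`, `fvc`), each with the six covariate terms plus `m1_latent` and
#'   `height_cm`.
#' @param sigma_height positive residual sd of height (cm).
#' @param sigma_outcomes residual covariance matrix of the outcomes (mL^2),
#'   symmetric positive definite (1x1 for the ratio model).
#' @return object of class `path_coefs`.
#' @export
path_coefs <- function(mediator, height, outcomes, sigma_height,
                       sigma_outcomes) {
  stopifnot(all(X4_TERMS %in% names(mediator)),
            all(c(X4_TERMS, "m1_latent") %in% names(height)))
  for (nm in names(outcomes))
    stopifnot(all(c(X6_TERMS, "m1_latent", "height_cm") %in%
                    names(outcomes[[nm]])))
  sigma_outcomes <- as.matrix(sigma_outcomes)
  K <- length(outcomes)
  if (!isTRUE(all.equal(dim(sigma_outcomes), c(K, K))))
    abort("sigma_outcomes dimension must match the number of outcomes")
  if (sigma_height <= 0) abort("sigma_height must be positive")
  ev <- eigen(sigma_outcomes, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("sigma_outcomes must be positive definite")
  structure(
    list(mediator = mediator[X4_TERMS],
         height = height[c(X4_TERMS, "m1_latent")],
         outcomes = lapply(outcomes, function(o)
           o[c(X6_TERMS, "m1_latent", "height_cm")]),
         sigma_height = sigma_height,
         sigma_outcomes = sigma_outcomes),
    class = "path_coefs"
  )
}

#' @export
print.path_coefs <- function(x, ...) {
  cat("<path_coefs> latent-probit serial mediation coefficients\n")
  cat(" mediator (probit):", paste(sprintf("%s=%.3g", names(x$mediator),
                                           x$mediator), collapse = ", "), "\n")
  cat(" height (cm):", paste(sprintf("%s=%.3g", names(x$height), x$height),
                             collapse = ", "), "\n")
  for (nm in names(x$outcomes))
    cat(" ", nm, ":", paste(sprintf("%s=%.3g", names(x$outcomes[[nm]]),
                                    x$outcomes[[nm]]), collapse = ", "), "\n")
  cat(" sigma_height:", signif(x$sigma_height, 4), "\n")
  invisible(x)
}

# pack structural coefficients into the reduced-form parameter vector used
# by the compiled likelihood (natural units)
structural_to_theta <- function(coefs) {
  K <- length(coefs$outcomes)
  a <- unname(coefs$mediator)
  h <- unname(coefs$height[X4_TERMS])
  d <- unname(coefs$height[["m1_latent"]])
  piM2 <- h + d * a
  pad <- function(v4) c(v4, 0, 0)  # x4 terms into x6 positions
  piY <- matrix(0, 6, K)
  b1 <- b2 <- numeric(K)
  for (k in seq_len(K)) {
    o <- coefs$outcomes[[k]]
    b1[k] <- o[["m1_latent"]]; b2[k] <- o[["height_cm"]]
    piY[, k] <- unname(o[X6_TERMS]) + (b1[k] + b2[k] * d) * pad(a) +
      b2[k] * pad(h)
  }
  L <- t(chol(coefs$sigma_outcomes))
  chol_par <- if (K == 1) log(L[1, 1]) else c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
  c(a, piM2, as.vector(piY), d, b1, b2, log(coefs$sigma_height), chol_par)
}

theta_to_structural <- function(theta, outcome_names) {
  K <- length(outcome_names)
  p <- 0
  take <- function(n) { v <- theta[(p + 1):(p + n)]; p <<- p + n; v }
  a <- take(4); piM2 <- take(4)
  piY <- matrix(take(6 * K), 6, K)
  d <- take(1); b1 <- take(K); b2 <- take(K)
  sigma_height <- exp(take(1))
  chol_par <- take(if (K == 1) 1 else 3)
  L <- if (K == 1) matrix(exp(chol_par), 1, 1) else
    matrix(c(exp(chol_par[1]), chol_par[2], 0, exp(chol_par[3])), 2, 2)
  h <- piM2 - d * a
  pad <- function(v4) c(v4, 0, 0)
  outcomes <- list()
  for (k in seq_len(K)) {
    ck <- piY[, k] - (b1[k] + b2[k] * d) * pad(a) - b2[k] * pad(h)
    outcomes[[outcome_names[k]]] <-
      setNames(c(ck, b1[k], b2[k]), c(X6_TERMS, "m1_latent", "height_cm"))
  }
  path_coefs(
    mediator = setNames(a, X4_TERMS),
    height = setNames(c(h, d), c(X4_TERMS, "m1_latent")),
    outcomes = outcomes,
    sigma_height = sigma_height,
    sigma_outcomes = L %*% t(L)
  )
}

# reparameterise a natural-units theta for data whose M2, Y and age columns
# were standardised (scaling: list(m_mu, m_sd, y_mu, y_sd, age_mu, age_sd));
# exact linear map, so the MLE is unaffected
theta_scale <- function(theta, K, scaling, invert = FALSE) {
  s <- scaling
  p <- 0
  take <- function(n) { v <- theta[(p + 1):(p + n)]; p <<- p + n; v }
  a <- take(4); piM2 <- take(4)
  piY <- matrix(take(6 * K), 6, K)
  d <- take(1); b1 <- take(K); b2 <- take(K)
  lsig2 <- take(1)
  chol_par <- take(if (K == 1) 1 else 3)
  L <- if (K == 1) matrix(exp(chol_par), 1, 1) else
    matrix(c(exp(chol_par[1]), chol_par[2], 0, exp(chol_par[3])), 2, 2)
  Sig <- L %*% t(L)
  if (!invert) {
    piM2 <- piM2 / s$m_sd; piM2[1] <- piM2[1] - s$m_mu / s$m_sd
    for (k in seq_len(K)) {
      v <- piY[, k]
      v[1] <- (v[1] + v[5] * s$age_mu - s$y_mu[k]) / s$y_sd[k]
      v[2:4] <- v[2:4] / s$y_sd[k]; v[6] <- v[6] / s$y_sd[k]
      v[5] <- v[5] * s$age_sd / s$y_sd[k]
      piY[, k] <- v
    }
    d <- d / s$m_sd
    b1 <- b1 / s$y_sd
    b2 <- b2 * s$m_sd / s$y_sd
    lsig2 <- lsig2 - log(s$m_sd)
    Sig <- diag(1 / s$y_sd, K) %*% Sig %*% diag(1 / s$y_sd, K)
  } else {
    piM2 <- piM2 * s$m_sd; piM2[1] <- piM2[1] + s$m_mu
    for (k in seq_len(K)) {
      v <- piY[, k]
      v[2:4] <- v[2:4] * s$y_sd[k]; v[6] <- v[6] * s$y_sd[k]
      age_nat <- v[5] * s$y_sd[k] / s$age_sd
      v[1] <- v[1] * s$y_sd[k] + s$y_mu[k] - age_nat * s$age_mu
      v[5] <- age_nat
      piY[, k] <- v
    }
    d <- d * s$m_sd
    b1 <- b1 * s$y_sd
    b2 <- b2 * s$y_sd / s$m_sd
    lsig2 <- lsig2 + log(s$m_sd)
    Sig <- diag(s$y_sd, K) %*% Sig %*% diag(s$y_sd, K)
  }
  Lo <- t(chol(Sig))
  chol_par <- if (K == 1) log(Lo[1, 1]) else
    c(log(Lo[1, 1]), Lo[2, 1], log(Lo[2, 2]))
  c(a, piM2, as.vector(piY), d, b1, b2, lsig2, chol_par)
}
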