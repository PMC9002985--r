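spec_pair <- model_spec("paternal")

test_that("starting values are deterministic and screen degenerate groups", {
  co <- medium_cohort()
  iv1 <- initial_values(co, spec_pair)
  iv2 <- initial_values(co, spec_pair)
  expect_identical(iv1, iv2)
  bad <- co
  bad$m1_overweight_prepuberty <- FALSE
  expect_error(initial_values(bad, spec_pair), "degenerate mediator")
})

test_that("starting values approximate the latent-observed oracle at scale", {
  co <- attach_latent_oracle(large_cohort())
  iv <- initial_values(co, spec_pair)$son
  or <- oracle_fit(co, spec_pair, "son")
  expect_lt(abs(iv$mediator[["before_puberty"]] -
                  or$mediator[["before_puberty"]]), 0.15)
  expect_lt(abs(iv$height[["before_puberty"]] -
                  or$height[["before_puberty"]]), 0.6)
  expect_lt(abs(iv$outcomes$fvc[["height_cm"]] -
                  or$outcomes$fvc[["height_cm"]]), 3)
})

test_that("closed-form likelihood matches a brute-force Monte Carlo integral", {
  toy <- tibble::tibble(
    offspring_id = paste0("T", 1:5), parent_id = paste0("T", 1:5),
    line = "paternal", sex = "son",
    age = c(20, 30, 40, 25, 35),
    ever_smoker = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    m1_overweight_prepuberty = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    height_cm = c(180, 175, 185, 178, 182),
    fev1_ml = c(4300, 4100, 4600, 4200, 4400),
    fvc_ml = c(5400, 5100, 5700, 5200, 5500),
    fev1_post_ml = NA_real_, fvc_post_ml = NA_real_,
    parent_edu_low = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    parent_exposure = c("before_puberty", "never", "never",
                        "at30_not_before", "never"))
  cf <- path_coefs(
    mediator = setNames(c(-0.8, 0.5, 0.1, 0.2),
                        serimed:::X4_TERMS),
    height = setNames(c(179, -3, -0.5, -1, 0.6),
                      c(serimed:::X4_TERMS, "m1_latent")),
    outcomes = list(
      fev1 = setNames(c(4000, -150, -20, -40, -5, -100, 40, 2),
                      c(serimed:::X6_TERMS, "m1_latent", "height_cm")),
      fvc = setNames(c(5000, -250, -40, -40, -6, -60, 55, 3),
                     c(serimed:::X6_TERMS, "m1_latent", "height_cm"))),
    sigma_height = 6,
    sigma_outcomes = matrix(c(300^2, 0.6 * 300 * 400,
                              0.6 * 300 * 400, 400^2), 2))
  ll <- observed_loglik(toy, spec_pair, "son", cf)

  # independent oracle: average the conditional density over latent draws
  set.seed(99)
  ndraw <- 1e6
  eps <- rnorm(ndraw)
  e1 <- as.numeric(toy$parent_exposure == "before_puberty")
  e2 <- as.numeric(toy$parent_exposure == "at30_not_before")
  edu <- as.numeric(toy$parent_edu_low)
  ll_mc <- 0; var_sum <- 0
  for (i in 1:5) {
    eta <- cf$mediator[["intercept"]] + cf$mediator[["before_puberty"]] * e1[i] +
      cf$mediator[["at30_not_before"]] * e2[i] +
      cf$mediator[["parent_edu_low"]] * edu[i]
    m1s <- eta + eps
    ind <- (m1s > 0) == toy$m1_overweight_prepuberty[i]
    mu2 <- cf$height[["intercept"]] + cf$height[["before_puberty"]] * e1[i] +
      cf$height[["at30_not_before"]] * e2[i] +
      cf$height[["parent_edu_low"]] * edu[i] +
      cf$height[["m1_latent"]] * m1s
    d2 <- dnorm(toy$height_cm[i], mu2, cf$sigma_height)
    muY <- sapply(cf$outcomes, function(o)
      o[["intercept"]] + o[["before_puberty"]] * e1[i] +
        o[["at30_not_before"]] * e2[i] + o[["parent_edu_low"]] * edu[i] +
        o[["age"]] * toy$age[i] + o[["ever_smoker"]] * toy$ever_smoker[i] +
        o[["m1_latent"]] * m1s + o[["height_cm"]] * toy$height_cm[i])
    res <- cbind(toy$fev1_ml[i] - muY[, 1], toy$fvc_ml[i] - muY[, 2])
    dy <- mvtnorm::dmvnorm(res, sigma = cf$sigma_outcomes)
    vals <- ind * d2 * dy
    Lhat <- mean(vals)
    ll_mc <- ll_mc + log(Lhat)
    var_sum <- var_sum + var(vals) / (ndraw * Lhat^2)
  }
  expect_lt(abs(ll - ll_mc), 3 * sqrt(var_sum))

  # Gauss-Hermite approximation of the same integral
  llq <- observed_loglik(toy, spec_pair, "son", cf, method = "quadrature",
                         gh_order = 41)
  expect_lt(abs(llq - ll), 0.15)
  expect_error(observed_loglik(toy, spec_pair, "son", cf,
                               method = "quadrature", gh_order = 9),
               "order below 11")
  expect_error(model_spec(quadrature_order = 7), "below 11")
})

test_that("log-likelihood decreases when the residual covariance is inflated", {
  co <- medium_cohort()
  fit <- fit_mediation(co, spec_pair)
  cf <- fit$groups$son$coefficients
  ll_hat <- observed_loglik(co, spec_pair, "son", cf)
  cf2 <- cf
  cf2$sigma_outcomes <- cf$sigma_outcomes * 2
  expect_lt(observed_loglik(co, spec_pair, "son", cf2), ll_hat)
})

test_that("outcome rescaling shifts the likelihood by the Jacobian constant", {
  co <- medium_cohort()
  fit <- fit_group_model(co, spec_pair, "son")
  cf <- fit$coefficients
  cfd <- cf
  for (oc in names(cfd$outcomes)) {
    keep <- setdiff(names(cfd$outcomes[[oc]]), "height_cm")
    cfd$outcomes[[oc]][keep] <- cfd$outcomes[[oc]][keep] / 100
    cfd$outcomes[[oc]][["height_cm"]] <- cf$outcomes[[oc]][["height_cm"]] / 100
  }
  cfd$sigma_outcomes <- cf$sigma_outcomes / 1e4
  cod <- co
  cod$fev1_ml <- co$fev1_ml / 100
  cod$fvc_ml <- co$fvc_ml / 100
  ll_ml <- observed_loglik(co, spec_pair, "son", cf)
  ll_dl <- observed_loglik(cod, spec_pair, "son", cfd)
  n <- sum(co$sex == "son")
  expect_equal(ll_dl, ll_ml + n * 2 * log(100), tolerance = 1e-8)
})

test_that("the fitted likelihood dominates the starting values", {
  co <- medium_cohort()
  iv <- initial_values(co, spec_pair)
  fit <- fit_mediation(co, spec_pair)
  for (g in c("son", "daughter")) {
    ll0 <- observed_loglik(co, spec_pair, g, iv[[g]])
    expect_gte(fit$groups[[g]]$logLik, ll0)
    expect_true(fit$groups[[g]]$converged)
  }
})

test_that("estimates are invariant to row order", {
  co <- medium_cohort()
  fit1 <- fit_mediation(co, spec_pair)
  set.seed(31); perm <- sample(nrow(co))
  fit2 <- fit_mediation(co[perm, ], spec_pair)
  expect_equal(fit1$groups$son$coefficients$mediator,
               fit2$groups$son$coefficients$mediator, tolerance = 1e-4)
  expect_equal(fit1$groups$daughter$coefficients$outcomes$fvc,
               fit2$groups$daughter$coefficients$outcomes$fvc,
               tolerance = 1e-4)
})

test_that("the ratio model returns a scalar residual variance", {
  co <- medium_cohort()
  fit <- fit_mediation(co, model_spec("paternal", outcomes = "ratio"))
  expect_equal(dim(fit$groups$son$coefficients$sigma_outcomes), c(1L, 1L))
  expect_named(fit$groups$son$coefficients$outcomes, "ratio")
  expect_true(all(vapply(fit$groups, `[[`, TRUE, "converged")))
})

test_that("outcome-equation estimates are scale-equivariant (mL to dL)", {
  co <- medium_cohort()
  cod <- co
  cod$fev1_ml <- co$fev1_ml / 100
  cod$fvc_ml <- co$fvc_ml / 100
  f1 <- fit_group_model(co, spec_pair, "son")
  f2 <- fit_group_model(cod, spec_pair, "son")
  expect_equal(f2$coefficients$mediator, f1$coefficients$mediator,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$height, f1$coefficients$height,
               tolerance = 1e-6)
  for (oc in c("fev1", "fvc")) {
    keep <- setdiff(names(f1$coefficients$outcomes[[oc]]), "height_cm")
    expect_equal(f2$coefficients$outcomes[[oc]][keep],
                 f1$coefficients$outcomes[[oc]][keep] / 100,
                 tolerance = 1e-6)
  }
})

test_that("a group-specific simulated effect stays in its group", {
  p <- default_generator_params("paternal")
  paths <- p$paths
  paths$son$fvc[["c1"]] <- -300
  paths$daughter$fvc[["c1"]] <- 0
  pars <- generator_params("paternal", p$marginals, paths, p$covariates,
                           p$offspring_dist)
  co <- generate_cohort(pars, 20000, seed = 88)
  fit <- fit_mediation(co, spec_pair)
  son_c1 <- fit$groups$son$coefficients$outcomes$fvc[["before_puberty"]]
  dau_c1 <- fit$groups$daughter$coefficients$outcomes$fvc[["before_puberty"]]
  expect_lt(son_c1, -180)
  expect_lt(abs(dau_c1), 120)
})

test_that("estimation error shrinks with the sample size", {
  p <- default_generator_params("paternal")
  err <- function(co) {
    fit <- fit_mediation(co, spec_pair)
    tot <- 0
    for (g in c("son", "daughter")) {
      est <- fit$groups[[g]]$coefficients
      tru <- p$coefficients[[g]]
      tot <- tot +
        sum(((est$mediator - tru$mediator))^2) +
        sum(((est$height - tru$height) / 2)^2) +
        sum(((est$outcomes$fvc - tru$outcomes$fvc) / 50)^2)
    }
    tot
  }
  e_small <- err(generate_cohort(p, 2000, seed = 55))
  e_large <- err(large_cohort())
  expect_lt(e_large, e_small)
})

test_that("oracle fit recovers the height equation exactly when noiseless", {
  co <- medium_cohort()
  cow <- attach_latent_oracle(co)
  tru <- attr(co, "params")$coefficients$son
  # rebuild height as the exact structural mean given the latent mediator
  e1 <- as.numeric(cow$parent_exposure == "before_puberty")
  e2 <- as.numeric(cow$parent_exposure == "at30_not_before")
  h <- tru$height
  cow$height_cm <- h[["intercept"]] + h[["before_puberty"]] * e1 +
    h[["at30_not_before"]] * e2 +
    h[["parent_edu_low"]] * as.numeric(cow$parent_edu_low) +
    h[["m1_latent"]] * cow$m1_star
  of <- oracle_fit(cow[cow$sex == "son", ], spec_pair, "son")
  expect_equal(unname(of$height), unname(h), tolerance = 1e-8)
})

test_that("the maternal line fits with its own calibration", {
  co <- generate_cohort(default_generator_params("maternal"), 800, seed = 12)
  fit <- fit_mediation(co, model_spec("maternal"))
  expect_true(glance(fit)$converged)
  eff <- decompose_effects(fit)
  expect_equal(nrow(eff), 2 * 2 * 2 * 5)
  expect_true(all(is.finite(eff$estimate)))
})
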