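test_that("published paths reproduce the printed indirect-effect cells", {
  sons <- decompose_effects(published_paternal_coefs("son"), group = "son")
  daughters <- decompose_effects(published_paternal_coefs("daughter"),
                                 group = "daughter")
  cell <- function(tb, ct, oc, ef) {
    tb$estimate[tb$contrast == ct & tb$outcome == oc & tb$effect == ef]
  }
  bp <- "before_puberty"
  expect_equal(round_half_away(cell(sons, bp, "fev1", "nie_m2")), -144)
  expect_equal(round_half_away(cell(sons, bp, "fev1", "nie_m1")), 20)
  expect_equal(round_half_away(cell(sons, bp, "fev1", "nie_m1_m2")), 9)
  expect_equal(round_half_away(cell(sons, bp, "fvc", "nie_m1")), 30)
  expect_equal(round_half_away(cell(sons, bp, "fvc", "nie_m1_m2")), 13)
  expect_equal(round_half_away(cell(daughters, bp, "fvc", "nie_m2")), -87)
  expect_equal(round_half_away(cell(daughters, bp, "fvc", "nie_m1_m2")), -40)
})

test_that("additivity of the decomposition is exact for any coefficients", {
  for (s in 1:25) {
    cf <- random_path_coefs(s)
    eff <- decompose_effects(cf)
    tot <- eff$estimate[eff$effect == "total"]
    parts <- tapply(eff$estimate[eff$effect != "total"],
                    paste(eff$contrast, eff$outcome)[eff$effect != "total"],
                    sum)
    key <- paste(eff$contrast, eff$outcome)[eff$effect == "total"]
    scale <- max(1, abs(tot))
    expect_lt(max(abs(unname(parts[key]) - tot)) / scale, 1e-12)
  }
})

test_that("zero paths null the corresponding indirect effects", {
  cf <- random_path_coefs(7)
  zap <- function(cf, where, term) { cf[[where]][[term]] <- 0; cf }
  a0 <- cf
  a0$mediator[["before_puberty"]] <- 0
  e <- decompose_effects(a0, contrast = "before_puberty")
  expect_true(all(e$estimate[e$effect %in% c("nie_m1", "nie_m1_m2")] == 0))
  d0 <- cf
  d0$height[["m1_latent"]] <- 0
  e <- decompose_effects(d0)
  expect_true(all(e$estimate[e$effect == "nie_m1_m2"] == 0))
  h0 <- cf
  h0$height[["before_puberty"]] <- 0
  e <- decompose_effects(h0, contrast = "before_puberty")
  expect_true(all(e$estimate[e$effect == "nie_m2"] == 0))
})

test_that("the total effect equals the reduced-form exposure coefficient", {
  co <- large_cohort()
  p <- attr(co, "params")
  sons <- co[co$sex == "son", ]
  rf <- lm(fvc_ml ~ I(parent_exposure == "before_puberty") +
             I(parent_exposure == "at30_not_before") + parent_edu_low +
             age + ever_smoker, data = sons)
  tot <- decompose_effects(p$coefficients$son, group = "son")
  truth <- tot$estimate[tot$contrast == "before_puberty" &
                          tot$outcome == "fvc" & tot$effect == "total"]
  est <- coef(rf)[[2]]
  se <- summary(rf)$coefficients[2, 2]
  expect_lt(abs(est - truth), 3 * se)
  # and total_effect() is the exact sum of the four components
  eff <- decompose_effects(random_path_coefs(3))
  joined <- dplyr::inner_join(
    total_effect(eff), eff[eff$effect == "total", ],
    by = c("contrast", "group", "outcome", "effect"))
  expect_equal(nrow(joined), 4)
  expect_equal(joined$estimate.x, joined$estimate.y, tolerance = 1e-14)
})

test_that("sign of every effect is preserved under mL to dL rescale", {
  cf <- published_paternal_coefs("son")
  cfd <- cf
  for (oc in names(cfd$outcomes)) {
    cfd$outcomes[[oc]][c("intercept", "before_puberty", "at30_not_before",
                         "parent_edu_low", "age", "ever_smoker",
                         "m1_latent")] <-
      cfd$outcomes[[oc]][c("intercept", "before_puberty", "at30_not_before",
                           "parent_edu_low", "age", "ever_smoker",
                           "m1_latent")] / 100
    cfd$outcomes[[oc]][["height_cm"]] <- cfd$outcomes[[oc]][["height_cm"]] / 100
  }
  cfd$sigma_outcomes <- cf$sigma_outcomes / 1e4
  e_ml <- decompose_effects(cf)
  e_dl <- decompose_effects(cfd)
  expect_equal(e_dl$estimate, e_ml$estimate / 100, tolerance = 1e-12)
})

test_that("sons-minus-daughters differences reproduce the printed delta", {
  sons <- decompose_effects(published_paternal_coefs("son"), group = "son")
  daughters <- decompose_effects(published_paternal_coefs("daughter"),
                                 group = "daughter")
  delta <- group_difference(dplyr::bind_rows(sons, daughters))
  nde_fvc <- delta$delta[delta$contrast == "before_puberty" &
                           delta$outcome == "fvc" & delta$effect == "nde"]
  expect_equal(nde_fvc, -262 - 78)
  # antisymmetry under swapping the groups
  swapped <- dplyr::bind_rows(
    dplyr::mutate(sons, group = "daughter"),
    dplyr::mutate(daughters, group = "son"))
  delta_sw <- group_difference(swapped)
  expect_equal(delta_sw$delta, -delta$delta)
  # identical decompositions give all-zero differences
  same <- dplyr::bind_rows(sons, dplyr::mutate(sons, group = "daughter"))
  expect_true(all(group_difference(same)$delta == 0))
  # mismatched labels are an error
  expect_error(group_difference(sons,
                                dplyr::mutate(daughters, outcome = "x")),
               "mismatch")
})

test_that("mediation typology follows the significance flags", {
  expect_equal(as.character(classify_mediation(TRUE, TRUE, TRUE)),
               "complementary")
  expect_equal(as.character(classify_mediation(FALSE, TRUE)),
               "indirect_only")
  expect_equal(as.character(classify_mediation(TRUE, FALSE)),
               "direct_only")
  expect_equal(as.character(classify_mediation(FALSE, FALSE)),
               "non_mediation")
  expect_equal(as.character(classify_mediation(TRUE, TRUE, FALSE)),
               "non_mediation")
})
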