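# Shared fixtures, all built in code.

# hand-written ten-offspring cohort used for descriptive and IO checks
tiny_cohort <- function() {
  tibble::tibble(
    offspring_id = sprintf("O%02d", 1:10),
    parent_id = c("F1", "F1", "F2", "F3", "F3", "F4", "F5", "F6", "F7", "F8"),
    line = "paternal",
    sex = rep(c("son", "daughter"), 5),
    age = c(25, 30, 41, 33, 22, 19, 48, 27, 35, 29),
    ever_smoker = c(TRUE, FALSE, FALSE, TRUE, FALSE,
                    FALSE, TRUE, FALSE, FALSE, TRUE),
    m1_overweight_prepuberty = c(FALSE, TRUE, FALSE, FALSE, TRUE,
                                 FALSE, FALSE, TRUE, FALSE, FALSE),
    height_cm = c(182, 167, 178, 185, 170, 176, 181, 163, 188, 165),
    fev1_ml = c(4400, 3300, 4100, 4600, 3400, 4200, 3900, 3100, 4800, 3200),
    fvc_ml = c(5500, 4000, 5100, 5700, 4200, 5200, 4900, 3800, 6000, 3900),
    fev1_post_ml = c(4500, NA, 4200, 4700, NA, 4300, 4000, NA, 4900, 3300),
    fvc_post_ml = c(5480, NA, 5080, 5680, NA, 5180, 4880, NA, 5980, 3880),
    parent_edu_low = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                       FALSE, TRUE, FALSE, FALSE, FALSE),
    parent_exposure = c("never", "never", "before_puberty", "never", "never",
                        "at30_not_before", "never", "never", "never",
                        "before_puberty")
  )
}

# cohort matching the published paternal-line counts: 308 fathers of whom 37
# were overweight before puberty and 32 at age 30 only; 420 offspring of
# whom 91 report prepubertal overweight
table1_paternal_fixture <- function() {
  n_parents <- 308
  parent_exposure <- rep(c("before_puberty", "at30_not_before", "never"),
                         c(37, 32, 239))
  extra <- 420 - n_parents
  parent_of <- c(seq_len(n_parents), seq_len(extra))
  ow <- rep(FALSE, 420); ow[seq_len(91)] <- TRUE
  tibble::tibble(
    offspring_id = sprintf("C%03d", 1:420),
    parent_id = sprintf("F%03d", parent_of),
    line = "paternal",
    sex = rep(c("son", "daughter"), length.out = 420),
    age = rep(seq(18, 51, length.out = 60), length.out = 420),
    ever_smoker = rep(c(TRUE, FALSE, FALSE, FALSE), length.out = 420),
    m1_overweight_prepuberty = ow,
    height_cm = rep(seq(150, 200, length.out = 35), length.out = 420),
    fev1_ml = rep(seq(2500, 5500, length.out = 70), length.out = 420),
    fvc_ml = rep(seq(3500, 7000, length.out = 70), length.out = 420),
    parent_edu_low = rep(c(TRUE, FALSE), c(26, 282))[parent_of],
    parent_exposure = parent_exposure[parent_of]
  )
}

# published paternal-line structural paths (point estimates); intercepts,
# covariate terms and scales set to neutral values irrelevant to the
# decomposition
published_paternal_coefs <- function(group = c("son", "daughter")) {
  group <- match.arg(group)
  if (group == "son") {
    a <- c(0.56, 0.07); h <- c(-3.42, -0.17); d <- 0.37
    fev1 <- c(-164, -15, 36, 42); fvc <- c(-262, -43, 54, 61)
  } else {
    a <- c(0.83, -0.02); h <- c(-2.11, -0.2); d <- -1.17
    fev1 <- c(26, 51, 32, 30); fvc <- c(78, 64, 48, 41)
  }
  out <- function(v) setNames(c(0, v[1], v[2], 0, 0, 0, v[3], v[4]),
                              c("intercept", "before_puberty",
                                "at30_not_before", "parent_edu_low", "age",
                                "ever_smoker", "m1_latent", "height_cm"))
  path_coefs(
    mediator = setNames(c(0, a, 0),
                        c("intercept", "before_puberty", "at30_not_before",
                          "parent_edu_low")),
    height = setNames(c(0, h, 0, d),
                      c("intercept", "before_puberty", "at30_not_before",
                        "parent_edu_low", "m1_latent")),
    outcomes = list(fev1 = out(fev1), fvc = out(fvc)),
    sigma_height = 6,
    sigma_outcomes = diag(c(500^2, 600^2))
  )
}

# generator parameters with every exposure path set to zero (null model for
# coverage checks); mediator-to-outcome paths keep their defaults
null_generator_params <- function(line = "paternal") {
  p <- default_generator_params(line)
  paths <- p$paths
  for (g in c("son", "daughter")) {
    paths[[g]]$a <- c(0, 0)
    paths[[g]]$h <- c(0, 0)
    paths[[g]]$fev1[c("c1", "c2")] <- 0
    paths[[g]]$fvc[c("c1", "c2")] <- 0
  }
  generator_params(line, p$marginals, paths, p$covariates, p$offspring_dist)
}

# memoised medium/large synthetic cohorts shared across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, code) {
  if (!exists(key, .fixture_cache)) assign(key, force(code), .fixture_cache)
  get(key, .fixture_cache)
}

medium_cohort <- function() cached("medium", {
  generate_cohort(default_generator_params("paternal"), 2000, seed = 401)
})

large_cohort <- function() cached("large", {
  generate_cohort(default_generator_params("paternal"), 50000, seed = 402)
})

random_path_coefs <- function(rng_seed) {
  with_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); force(code)
  }
  with_seed(rng_seed, {
    out <- function() setNames(rnorm(8, 0, 50), c("intercept",
      "before_puberty", "at30_not_before", "parent_edu_low", "age",
      "ever_smoker", "m1_latent", "height_cm"))
    path_coefs(
      mediator = setNames(rnorm(4), c("intercept", "before_puberty",
                                      "at30_not_before", "parent_edu_low")),
      height = setNames(rnorm(5, 0, 2), c("intercept", "before_puberty",
                                          "at30_not_before",
                                          "parent_edu_low", "m1_latent")),
      outcomes = list(fev1 = out(), fvc = out()),
      sigma_height = exp(rnorm(1)),
      sigma_outcomes = { A <- matrix(rnorm(4), 2); crossprod(A) + diag(2) }
    )
  })
}
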