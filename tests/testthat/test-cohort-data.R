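test_that("silhouette coding applies the sex-specific cut-offs", {
  expect_true(code_overweight_from_silhouette("male", 5))
  expect_true(code_overweight_from_silhouette("female", 4))
  expect_false(code_overweight_from_silhouette("male", 4))
  expect_false(code_overweight_from_silhouette("female", 3))
  # monotone in score for each sex
  for (sx in c("male", "female")) {
    coded <- code_overweight_from_silhouette(rep(sx, 9), 1:9)
    expect_true(all(diff(coded) >= 0))
  }
  expect_error(code_overweight_from_silhouette("male", 0), "1\\.\\.9")
  expect_error(code_overweight_from_silhouette("female", 10), "1\\.\\.9")
})

test_that("exposure categories are exhaustive, exclusive and prioritised", {
  expect_equal(as.character(derive_exposure_category(TRUE, FALSE, TRUE)),
               "before_puberty")
  expect_equal(as.character(derive_exposure_category(FALSE, FALSE, TRUE)),
               "at30_not_before")
  expect_equal(as.character(derive_exposure_category(FALSE, FALSE, FALSE)),
               "never")
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE))
  cats <- derive_exposure_category(grid$a, grid$b, grid$c)
  expect_false(anyNA(cats))
  expect_setequal(levels(cats),
                  c("before_puberty", "at30_not_before", "never"))
  # any missing flag leaves the category undefined
  expect_true(is.na(derive_exposure_category(NA, FALSE, TRUE)))
})

test_that("read/write round-trips a cohort file bit-exactly", {
  tc <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(write_cohort(validate_cohort(tc), path))
  back <- suppressMessages(read_cohort(path))
  orig <- suppressMessages(validate_cohort(tc))
  expect_equal(as.list(back), as.list(orig),
               ignore_attr = TRUE)  # identical values columnwise
  # booleans are serialised as 0/1 and enums as lowercase strings
  raw <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(raw$ever_smoker %in% 0:1))
  expect_true(all(raw$parent_exposure %in%
                    c("before_puberty", "at30_not_before", "never")))
  expect_equal(names(raw)[1:2], c("offspring_id", "parent_id"))
})

test_that("validation drops incomplete rows with logged reasons", {
  tc <- tiny_cohort()
  tc$height_cm[7] <- NA
  expect_message(out <- validate_cohort(tc), "DROPPED 1 rows: missing height")
  expect_equal(nrow(out), 9)
  # post-bronchodilator fields must come in pairs
  tc2 <- tiny_cohort()
  tc2$fvc_post_ml[1] <- NA
  expect_message(out2 <- validate_cohort(tc2),
                 "DROPPED 1 rows: post-bronchodilator")
  expect_equal(nrow(out2), 9)
})

test_that("structural file problems are hard errors", {
  tc <- tiny_cohort()
  tc$offspring_id[2] <- tc$offspring_id[1]
  expect_error(validate_cohort(tc), "duplicate offspring_id")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_cohort()[, -which(names(tiny_cohort()) == "age")],
                   path)
  expect_error(suppressMessages(read_cohort(path)), "missing mandatory")
  empty <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_cohort()[0, ], empty)
  expect_error(suppressMessages(read_cohort(empty)), "empty")
  one_parent_two_lines <- tiny_cohort()
  one_parent_two_lines$line[2] <- "maternal"
  expect_error(validate_cohort(one_parent_two_lines), "more than one line")
})

test_that("silhouette columns are coded when flags are absent", {
  tc <- tiny_cohort()
  tc$m1_overweight_prepuberty <- NULL
  tc$silhouette_offspring_age8 <- c(2, 5, 3, 3, 6, 2, 3, 4, 2, 3)
  tc$silhouette_offspring_puberty <- c(3, 4, 4, 3, 5, 3, 4, 5, 4, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tc, path)
  out <- suppressMessages(read_cohort(path))
  # male cut-off 5, female cut-off 4, overweight if met at either stage
  expected <- ifelse(tc$sex == "son",
                     tc$silhouette_offspring_age8 >= 5 |
                       tc$silhouette_offspring_puberty >= 5,
                     tc$silhouette_offspring_age8 >= 4 |
                       tc$silhouette_offspring_puberty >= 4)
  expect_equal(out$m1_overweight_prepuberty, expected)
})

test_that("descriptive summary reproduces hand-computed statistics", {
  tc <- suppressMessages(validate_cohort(tiny_cohort()))
  sm <- summarize_cohort(tc, "paternal")
  tot <- sm[sm$group == "total", ]
  expect_equal(tot$mean[tot$variable == "height_cm"], mean(tc$height_cm))
  expect_equal(tot$sd[tot$variable == "fev1_ml"], sd(tc$fev1_ml))
  expect_equal(tot$median[tot$variable == "age"], median(tc$age))
  # a group of identical heights has sd 0
  tc2 <- tc
  tc2$height_cm <- 175
  sm2 <- summarize_cohort(tc2, "paternal")
  expect_equal(sm2$sd[sm2$variable == "height_cm" & sm2$group == "total"], 0)
  # exposure-category counts sum to the parent total
  expo <- sm[sm$group == "total" & grepl("^overweight_", sm$variable) &
               sm$generation == "parent", ]
  expect_equal(sum(expo$count), sm$count[sm$variable == "n_parents" &
                                           sm$group == "total"])
  expect_error(summarize_cohort(tc, "maternal"), "maternal")
})

test_that("prevalences use one-decimal half-away-from-zero rounding", {
  expect_equal(round_half_away(c(12.04, 12.05, -12.05), 1),
               c(12.0, 12.1, -12.1))
  fx <- suppressMessages(validate_cohort(table1_paternal_fixture()))
  sm <- summarize_cohort(fx, "paternal")
  fathers <- sm[sm$generation == "parent" & sm$group == "total" &
                  sm$variable == "overweight_before_puberty", ]
  expect_equal(fathers$prevalence, 12.0)
  expect_equal(fathers$count, 37)
  offspring <- sm[sm$generation == "offspring" & sm$group == "total" &
                    sm$variable == "overweight_prepuberty", ]
  expect_equal(offspring$prevalence, 21.7)
  expect_equal(offspring$count, 91)
})

test_that("the shipped synthetic example cohort reads cleanly", {
  path <- system.file("extdata", "synthetic-cohort-paternal.csv",
                      package = "serimed")
  co <- suppressMessages(read_cohort(path))
  expect_s3_class(co, "cohort_tbl")
  expect_gt(nrow(co), 150)
  expect_setequal(as.character(unique(co$line)), "paternal")
})
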