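profile_b <- dplyr::filter(default_profiles("remission"), label == "B")

test_that("zero noise and no missingness reproduce the mean curve exactly", {
  prof <- dplyr::mutate(profile_b, sd = 0)
  tr <- generate_trajectory(prof, n = 3, censor_hazard = 0,
                            sporadic_missing_rate = 0, seed = 1)
  expect_true(all(tr$observed))
  expect_equal(tr$cortisol, rep(prof$mean, 3))
})

test_that("marginal moments are recovered over many uncensored draws", {
  n <- 5000
  tr <- generate_trajectory(
    profile_b, n = n,
    censor_hazard = 0, sporadic_missing_rate = 0,
    truncation_floor = -Inf, seed = 20
  )
  by_t <- tr |>
    dplyr::group_by(hours) |>
    dplyr::summarise(m = mean(cortisol), s = sd(cortisol))
  # 4 Monte-Carlo standard errors: SE(mean) = sd/sqrt(n), SE(sd) ~ sd/sqrt(2n)
  expect_true(all(abs(by_t$m - profile_b$mean) <=
                    4 * profile_b$sd / sqrt(n)))
  expect_true(all(abs(by_t$s - profile_b$sd) <=
                    4 * profile_b$sd / sqrt(2 * n)))
})

test_that("patient intercept induces positive within-curve correlation", {
  tr <- generate_trajectory(
    profile_b, n = 2000, patient_effect_sd_fraction = 0.5,
    censor_hazard = 0, sporadic_missing_rate = 0,
    truncation_floor = -Inf, seed = 3
  )
  wide <- tidyr::pivot_wider(tr[, c("patient_id", "hours", "cortisol")],
                             names_from = hours, values_from = cortisol)
  r <- cor(wide$`6`, wide$`12`)
  expect_gt(r, 0.15) # theoretical value f^2 = 0.25
  expect_lt(r, 0.35)
})

test_that("degenerate generator arguments error", {
  expect_error(
    generate_trajectory(profile_b, patient_effect_sd_fraction = 1.2),
    "negative"
  )
  expect_error(generate_cohort(2, default_profiles("remission"), seed = 1),
               "at least the number of profiles")
  expect_error(
    generate_cohort(77, counts = c(20, 20, 20), seed = 1),
    "sum to"
  )
})

test_that("cohorts are bit-identical under a repeated seed", {
  a <- generate_cohort(40, counts = NULL, seed = 123)
  b <- generate_cohort(40, counts = NULL, seed = 123)
  expect_identical(a, b)
  c <- generate_cohort(40, counts = NULL, seed = 124)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("fixed counts produce exactly the requested cluster sizes", {
  co <- generate_cohort(77, counts = c(23, 15, 39), seed = 7)
  tab <- table(co$true_labels$true_label)
  expect_equal(unname(tab[c("A", "B", "C")]), c(23, 15, 39),
               ignore_attr = TRUE)
})

test_that("no observed value sits strictly after the steroid time", {
  co <- generate_cohort(200, censor_hazard = 0.3, seed = 5)
  joined <- dplyr::left_join(co$measurements, co$steroids, by = "patient_id")
  violations <- joined |>
    dplyr::filter(!is.na(steroid_hours), hours > steroid_hours, observed)
  expect_equal(nrow(violations), 0)
})

test_that("observed counts are non-increasing under pure censoring", {
  co <- generate_cohort(150, censor_hazard = 0.25,
                        sporadic_missing_rate = 0, seed = 9)
  counts <- co$measurements |>
    dplyr::group_by(hours) |>
    dplyr::summarise(n = sum(observed)) |>
    dplyr::arrange(hours)
  expect_true(all(diff(counts$n) <= 0))
})

test_that("no missingness mechanisms means a fully observed mask", {
  tr <- generate_trajectory(profile_b, n = 50, censor_hazard = 0,
                            sporadic_missing_rate = 0, seed = 2)
  expect_true(all(tr$observed))
  expect_true(all(is.na(tr$steroid_hours)))
})

test_that("cohort CSVs round-trip through the package readers", {
  co <- generate_cohort(25, seed = 31)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  meas <- read_measurements(paths[["measurements"]])
  orig <- dplyr::left_join(co$measurements, co$steroids, by = "patient_id")
  expect_equal(meas$cortisol, orig$cortisol, tolerance = 1e-9)
  expect_equal(meas$observed, orig$observed)
  covs <- read_covariates(paths[["covariates"]])
  expect_equal(covs$age, co$covariates$age, tolerance = 1e-9)
  expect_equal(nrow(covs), 25)
})
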