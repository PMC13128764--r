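test_that("grid binning snaps, averages, and drops out-of-range measurements", {
  # exact grid times pass through unchanged
  m <- toy_measurements(c(10, 20, 30), hours = c(6, 12, 18))
  out <- bin_to_grid(m)
  expect_equal(out$hours, c(6, 12, 18))
  expect_equal(out$cortisol, c(10, 20, 30))

  # nearest-grid arithmetic with the half-open [t-3, t+3) window
  m2 <- toy_measurements(c(10, 20), hours = c(7, 11))
  out2 <- bin_to_grid(m2)
  expect_equal(out2$hours, c(6, 12))
  m3 <- toy_measurements(c(1, 2), hours = c(9, 8.99))
  out3 <- bin_to_grid(m3)
  expect_equal(out3$hours[out3$cortisol == 1], 12) # 9 is in [9, 15)
  expect_equal(out3$hours[out3$cortisol == 2], 6)

  # two measurements in one bin are averaged
  m4 <- toy_measurements(c(20, 30), hours = c(5.5, 6.5))
  out4 <- bin_to_grid(m4)
  expect_equal(nrow(out4), 1)
  expect_equal(out4$cortisol, 25)

  # beyond the last grid point + 3 h: dropped with a message
  m5 <- toy_measurements(c(1, 2), hours = c(96, 100))
  expect_message(out5 <- bin_to_grid(m5), "Dropping 1")
  expect_equal(out5$hours, 96)

  expect_error(bin_to_grid(toy_measurements(1, hours = -2)), "non-negative")
})

test_that("steroid censoring removes values strictly after the steroid time", {
  m <- toy_measurements(1:6, hours = seq(6, 36, 6))

  none <- censor_after_steroids(
    m, tibble::tibble(patient_id = "P1", steroid_hours = NA_real_)
  )
  expect_equal(none$cortisol, 1:6)

  at24 <- censor_after_steroids(
    m, tibble::tibble(patient_id = "P1", steroid_hours = 24)
  )
  expect_equal(at24$cortisol[at24$hours <= 24], 1:4)
  expect_true(all(is.na(at24$cortisol[at24$hours > 24])))

  at0 <- censor_after_steroids(
    m, tibble::tibble(patient_id = "P1", steroid_hours = 0)
  )
  expect_true(all(is.na(at0$cortisol)))
})

test_that("trajectory features follow the 6 h / 18 h definitions", {
  f <- derive_features(toy_measurements(c(30, 18), hours = c(6, 18)))
  expect_equal(f$initial_cortisol, 30)
  expect_equal(f$descent_velocity, 1)

  flat <- derive_features(toy_measurements(rep(10, 6), hours = seq(6, 36, 6)))
  expect_equal(flat$descent_velocity, 0)
  expect_equal(flat$nadir_cortisol, 10)

  # rising curve: negative velocity (decline is positive by convention)
  rising <- derive_features(toy_measurements(c(25, 31), hours = c(6, 18)))
  expect_equal(rising$descent_velocity, -0.5)

  # missing 18 h: velocity undefined, nadir still available
  m18 <- derive_features(toy_measurements(c(25, NA, 7),
                                          hours = c(6, 18, 24)))
  expect_true(is.na(m18$descent_velocity))
  expect_equal(m18$nadir_cortisol, 7)

  # nothing observed inside the window: all features missing
  empty <- derive_features(
    toy_measurements(c(NA, NA), hours = c(6, 12))
  )
  expect_true(all(is.na(empty[, -1])))
})

test_that("features never use post-steroid values", {
  # adversarial curve: the global minimum sits after steroid start
  m <- toy_measurements(c(30, 20, 1, 0.5), hours = c(6, 12, 18, 24))
  cens <- censor_after_steroids(
    m, tibble::tibble(patient_id = "P1", steroid_hours = 12)
  )
  f <- derive_features(cens)
  expect_equal(f$nadir_cortisol, 20)
  expect_true(is.na(f$descent_velocity)) # 18 h value was censored
})

test_that("matrix pivoting preserves values and drops empty patients", {
  m <- dplyr::bind_rows(
    toy_measurements(c(10, 20), hours = c(6, 12), id = "P1"),
    toy_measurements(c(NA, NA), hours = c(6, 12), id = "P2"),
    toy_measurements(c(5, NA), hours = c(6, 12), id = "P3")
  )
  expect_message(xm <- as_cortisol_matrix(m), "Dropping 1")
  expect_equal(dim(xm), c(2, 2))
  expect_equal(xm$values["P1", ], c(`6` = 10, `12` = 20))
  expect_true(is.na(xm$values["P3", "12"]))
})
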