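test_that("peak-to-peak amplitude matches the generator ground truth", {
  out <- simulate_epr_series(seed = 21, raw_curves = TRUE)
  for (i in seq(1, length(out$curves), by = 5)) {
    cv <- out$curves[[i]]
    expect_equal(peak_to_peak(cv$field_mT, cv$signal),
                 attr(cv, "amplitude"), tolerance = 0.01)
  }
  # linearity in the signal
  cv <- out$curves[[1]]
  expect_equal(peak_to_peak(cv$field_mT, 2 * cv$signal),
               2 * peak_to_peak(cv$field_mT, cv$signal))
  expect_error(peak_to_peak(1:10, rep(0, 10)), "flat")
  expect_error(peak_to_peak(seq(0, 1, length.out = 50),
                            sin(seq(0, pi, length.out = 50))),
               "fewer than 3")
})

test_that("additive-dose series validation", {
  expect_error(additive_dose_series("s", c(0, 50), c(1, 2)),
               "at least 3 distinct")
  expect_error(additive_dose_series("s", c(10, 50, 100), 1:3),
               "first added dose")
  ok <- additive_dose_series("s", c(0, 50, 100), c(1, 1.2, 1.4))
  expect_s3_class(ok, "kv_additive_series")
})

test_that("the additive-dose fit is exact on noiseless data", {
  d <- c(0, 50, 100, 150, 200)
  amp <- 0.02 * (150 + d)
  fit <- fit_additive_dose(additive_dose_series("s", d, amp))
  expect_equal(fit$d0_Gy, 150, tolerance = 1e-9)
  expect_equal(fit$sigma_Gy, 0, tolerance = 1e-6)
  expect_equal(fit$slope, 0.02, tolerance = 1e-9)
})

test_that("the fit is equivariant under dose shifts and amplitude scaling", {
  ser <- simulate_epr_series(d0_Gy = 194, seed = 33)
  f0 <- fit_additive_dose(ser)
  shifted <- ser; shifted$added_dose_Gy <- shifted$added_dose_Gy + 25
  class(shifted) <- class(ser)
  f1 <- fit_additive_dose(shifted)
  expect_equal(f1$d0_Gy, f0$d0_Gy - 25, tolerance = 1e-9)
  scaled <- ser; scaled$amplitude <- scaled$amplitude * 7
  class(scaled) <- class(ser)
  f2 <- fit_additive_dose(scaled)
  expect_equal(f2$d0_Gy, f0$d0_Gy, tolerance = 1e-9)
})

test_that("a non-responsive sample raises an estimation error", {
  d <- c(0, 50, 100)
  ser <- additive_dose_series("s", d, c(3, 2, 1))
  expect_error(fit_additive_dose(ser), "non-positive slope")
})

test_that("replicate-level and mean-level fits give the same dose for balanced data", {
  ser <- simulate_epr_series(seed = 12, replicates = 4)
  fm <- fit_additive_dose(ser)
  fr <- fit_additive_dose(ser, use_replicates = TRUE)
  expect_equal(fm$d0_Gy, fr$d0_Gy, tolerance = 1e-9)
})

test_that("cohort statistics agree with a direct hand computation", {
  df <- data.frame(
    mouse_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
    side = rep(c("left", "right"), 3),
    dose_Gy = c(200, 180, 210, 210, NA, 150),
    sigma_Gy = c(10, 9, 11, 11, NA, 8),
    missing = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  st <- cohort_statistics(cohort_table(df))
  d <- c(200, 180, 210, 210, 150)
  expect_equal(unname(st$combined["mean"]), mean(d))
  expect_equal(unname(st$combined["sd"]), sd(d))
  expect_equal(unname(st$right["mean"]), mean(c(180, 210, 150)))
  # pair CVs only for complete pairs (m1, m2)
  expect_length(st$pair_cv_pct, 2)
  expect_equal(unname(st$pair_cv_pct["m1"]),
               100 * (20 / sqrt(2)) / 190)
  expect_equal(unname(st$pair_cv_pct["m2"]), 0)
  cf <- cohort_conversion_factor(st, k_air_Gy = mean(d))
  expect_equal(cf$value[cf$group == "combined"], 1)
})

test_that("conversion factors scale linearly with dose", {
  co <- bone_dose_cohort()
  st1 <- cohort_statistics(co)
  co2 <- co; co2$dose_Gy <- co2$dose_Gy * 2
  class(co2) <- class(co)
  st2 <- cohort_statistics(co2)
  cf1 <- cohort_conversion_factor(st1)
  cf2 <- cohort_conversion_factor(st2)
  expect_equal(cf2$value, 2 * cf1$value)
})

test_that("identical left/right doses give zero intra-animal variability", {
  df <- data.frame(mouse_id = rep(c("a", "b"), each = 2),
                   side = rep(c("left", "right"), 2),
                   dose_Gy = c(100, 100, 140, 140),
                   sigma_Gy = 5, missing = FALSE)
  st <- cohort_statistics(cohort_table(df))
  expect_equal(unname(st$pair_cv_pct), c(0, 0))
  expect_equal(st$mean_pair_cv_pct, 0)
})
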