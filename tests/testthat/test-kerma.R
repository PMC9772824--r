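test_that("kerma ratio identities hold", {
  s <- test_spectrum()
  expect_equal(kerma_ratio(s, "air")$value, 1)
  s2 <- s; s2$fluence <- 3.7 * s$fluence
  expect_equal(kerma_ratio(s2, "cortical_bone")$value,
               kerma_ratio(s, "cortical_bone")$value)
})

test_that("kerma ratio equals the kerma-weighted mean of monoenergetic ratios", {
  s <- test_spectrum()
  keep <- s$fluence > 0
  e <- s$energy[keep]; fl <- s$fluence[keep]
  r_mono <- mass_coefficient("cortical_bone", e, "en") /
    mass_coefficient("air", e, "en")
  w <- fl * e * mass_coefficient("air", e, "en")
  expect_equal(kerma_ratio(s, "cortical_bone")$value,
               sum(w * r_mono) / sum(w), tolerance = 1e-12)
})

test_that("hardening the beam lowers the bone enhancement", {
  s <- test_spectrum()
  r0 <- kerma_ratio(s, "cortical_bone")$value
  r1 <- kerma_ratio(filter_spectrum(s, "copper", 0.3), "cortical_bone")$value
  expect_lt(r1, r0)
  # photoelectric Z-dependence fades with energy
  r200 <- mass_coefficient("cortical_bone", 199, "en") /
    mass_coefficient("air", 199, "en")
  r40 <- mass_coefficient("cortical_bone", 40, "en") /
    mass_coefficient("air", 40, "en")
  expect_lt(r200, r40)
})

test_that("dose conversion is a plain product", {
  expect_equal(dose_from_air_kerma(30, 6.5), 195)
  expect_equal(dose_from_air_kerma(0, 6.5), 0)
  expect_equal(dose_from_air_kerma(30, 1), 30)
  s <- test_spectrum()
  cf <- kerma_ratio(s, "cortical_bone")
  expect_equal(dose_from_air_kerma(30, cf), 30 * cf$value)
  expect_error(dose_from_air_kerma(-1, 6.5), ">= 0")
})

test_that("composition scan is monotone in calcium and density behaves as expected", {
  s <- test_spectrum()
  ca <- composition_sensitivity_scan(s, "cortical_bone", "calcium_fraction",
                                     c(0, 0.1, 0.225, 0.3))
  expect_true(all(diff(ca$kerma_ratio) > 0))
  expect_lt(ca$kerma_ratio[1], kerma_ratio(s, "cortical_bone")$value)
  de <- composition_sensitivity_scan(s, "cortical_bone", "density",
                                     c(0.1, 0.3, 0.8, 1.18, 1.5, 1.92))
  # kerma ratio is per unit mass: invariant under density
  expect_equal(diff(range(de$kerma_ratio)), 0, tolerance = 1e-9)
  expect_true(all(diff(de$attenuation_pct) > 0))
  # across low to nominal bone densities the 7 mm attenuation spans the
  # printed 10-28% variability band
  expect_lt(min(de$attenuation_pct), 10)
  expect_gt(max(de$attenuation_pct), 28)
  expect_error(composition_sensitivity_scan(s, "cortical_bone",
                                            "calcium_fraction", 1.5),
               "\\[0, 1\\]")
  expect_error(composition_sensitivity_scan(s, "cortical_bone", "density",
                                            -2), "positive")
})
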