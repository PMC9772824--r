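test_that("interpolation reproduces table nodes exactly and is log-log linear", {
  tab <- kvdosim:::kv_tables()$coeff$Cu
  # away from the K edge
  i <- which(abs(tab$energy_keV - 20) < 1e-9)
  expect_equal(mass_coefficient("Cu", 20, "total"), tab$total[i])
  expect_equal(mass_coefficient("Cu", 20, "en"), tab$en[i])
  # geometric mean of adjacent nodes -> geometric mean of values
  e1 <- tab$energy_keV[i]; e2 <- tab$energy_keV[i + 1]
  v <- mass_coefficient("Cu", sqrt(e1 * e2), "total")
  expect_equal(v, sqrt(tab$total[i] * tab$total[i + 1]), tolerance = 1e-12)
})

test_that("energy-absorption never exceeds total attenuation", {
  en <- c(seq(2, 60, by = 2), 80, 120, 199)
  for (m in c("air", "water", "soft_tissue", "cortical_bone",
              "trabecular_bone", "bone_marrow", "copper")) {
    expect_true(all(mass_coefficient(m, en, "en") <=
                      mass_coefficient(m, en, "total") * (1 + 1e-9)),
                info = m)
  }
})

test_that("partial coefficients sum to the total", {
  en <- c(5, 20, 40, 80, 150)
  for (m in c("soft_tissue", "cortical_bone", "copper")) {
    parts <- mass_coefficient(m, en, "photoelectric") +
      mass_coefficient(m, en, "compton") + mass_coefficient(m, en, "rayleigh")
    expect_equal(parts, mass_coefficient(m, en, "total"), tolerance = 0.01)
  }
})

test_that("photoelectric coefficient falls monotonically between edges", {
  # Cu between its K edge (8.98 keV) and 200 keV
  en <- seq(9.5, 199, length.out = 40)
  v <- mass_coefficient("Cu", en, "photoelectric")
  expect_true(all(diff(v) < 0))
})

test_that("cortical bone to air energy-absorption ratio matches standard tabulations", {
  # frozen from the shipped tables: ratio at 40 keV is ~6.6, and within
  # [5, 9] across the 30-50 keV band (bone dose enhancement factor)
  r40 <- mass_coefficient("cortical_bone", 40, "en") /
    mass_coefficient("air", 40, "en")
  expect_equal(r40, 6.61, tolerance = 0.02)
  for (e in seq(30, 50, by = 5)) {
    r <- mass_coefficient("cortical_bone", e, "en") /
      mass_coefficient("air", e, "en")
    expect_gt(r, 5); expect_lt(r, 9)
  }
})

test_that("mixture rule is mass-fraction additive", {
  pure <- kv_material("pure_ca", 1, c(Ca = 1))
  expect_equal(mass_coefficient(pure, 30), mass_coefficient("Ca", 30))
  mix <- kv_material("mix", 1, c(Ca = 0.5, O = 0.5))
  expect_equal(mass_coefficient(mix, 30),
               (mass_coefficient("Ca", 30) + mass_coefficient("O", 30)) / 2)
})

test_that("raising the calcium fraction raises the photoelectric coefficient", {
  bone <- get_material("cortical_bone")
  fr <- bone$fractions
  fr["Ca"] <- fr["Ca"] + 0.05
  fr <- fr / sum(fr)
  rich <- kv_material("ca_rich", bone$density, fr)
  expect_gt(mass_coefficient(rich, 40, "photoelectric"),
            mass_coefficient(bone, 40, "photoelectric"))
})

test_that("linear attenuation scales with density and falls with energy", {
  m1 <- kv_material("m1", 1.0, c(O = 1))
  m2 <- kv_material("m2", 2.0, c(O = 1))
  expect_equal(linear_attenuation(m2, 40), 2 * linear_attenuation(m1, 40))
  # air is of order 1e-4..1e-3 1/cm at 40 keV
  expect_lt(linear_attenuation("air", 40), 1e-3)
  expect_gt(linear_attenuation("air", 40), 1e-5)
  expect_lt(linear_attenuation("copper", 60), linear_attenuation("copper", 30))
})

test_that("lookup errors are raised", {
  expect_error(mass_coefficient("Cu", 0.5), "outside")
  expect_error(mass_coefficient("Cu", 250), "outside")
  expect_error(get_material("kryptonite"), "unknown material")
  expect_error(kv_material("bad", 1, c(H = 0.5)), "sum to 1")
  expect_error(kv_material("bad", -1, c(H = 1)), "density")
})

test_that("relaxation data satisfy the physical invariants", {
  for (el in c("P", "S", "Ca", "Fe", "Cu")) {
    d <- element_data(el)
    expect_gt(d$K_fluorescence_yield, 0)
    expect_lt(d$K_fluorescence_yield, 1)
    expect_lt(d$KLL_auger_keV, d$K_edge_keV)
    expect_lt(d$K_alpha_keV, d$K_edge_keV)
    expect_gt(d$K_shell_fraction, 0.5)
    expect_lt(d$K_shell_fraction, 1)
  }
})
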