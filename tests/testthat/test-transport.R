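# shared small runs for this file
local({
  s <- test_spectrum()
  kv_test_env$het_small <- transport(heterogeneous_leg_phantom(), s,
                                     transport_config(2e5, seed = 101))
})

test_that("a fixed seed gives bit-identical transport results", {
  s <- test_spectrum()
  ph <- heterogeneous_leg_phantom()
  cfg <- transport_config(n_histories = 3e4, seed = 7)
  r1 <- transport(ph, s, cfg)
  r2 <- transport(ph, s, cfg)
  expect_identical(r1$cell_dose, r2$cell_dose)
  expect_identical(r1$electron_energy_hist, r2$electron_energy_hist)
  expect_identical(r1$energy, r2$energy)
  r3 <- transport(ph, s, transport_config(n_histories = 3e4, seed = 8))
  expect_false(identical(r1$cell_dose, r3$cell_dose))
})

test_that("energy is conserved history by history", {
  r <- kv_test_env$het_small
  expect_lt(abs(r$energy["incident"] - r$energy["deposited"] -
                  r$energy["escaped"]), 1e-6 * r$energy["incident"])
})

test_that("electron histogram totals equal electron production counts", {
  r <- kv_test_env$het_small
  for (m in colnames(r$counts)) {
    expect_equal(sum(r$electron_energy_hist[, m]), r$counts["electrons", m])
    expect_equal(sum(r$electron_path_hist[, m]), r$counts["electrons", m])
  }
})

test_that("photoelectric-only transport matches the analytic exponential", {
  mono <- make_spectrum(40, 1)
  ph <- homogeneous_phantom("cortical_bone", 70)
  r <- transport(ph, mono, transport_config(
    n_histories = 4e5, seed = 12, photoelectric_only = TRUE,
    local_deposition = TRUE, fluorescence = FALSE))
  mu <- linear_attenuation("cortical_bone", 40, "photoelectric") / 10  # 1/mm
  z <- seq(0, 7, by = 0.1)
  frac <- exp(-mu * z[-71]) - exp(-mu * z[-1])
  mass <- 1.92 * 30 * 10 * 0.1 / 1000
  expected <- 40 * frac / mass  # dose per history
  zscore <- (r$cell_dose - expected) / r$cell_dose_stderr
  expect_lt(max(abs(zscore)), 3)
})

test_that("doubling histories shrinks the statistical error by about sqrt(2)", {
  s <- test_spectrum()
  ph <- homogeneous_phantom("soft_tissue", 70)
  r1 <- transport(ph, s, transport_config(1e5, seed = 5))
  r2 <- transport(ph, s, transport_config(2e5, seed = 5))
  ratio <- mean(r1$cell_dose_stderr / r1$cell_dose) /
    mean(r2$cell_dose_stderr / r2$cell_dose)
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.75)
})

test_that("segment summaries behave on constructed doses", {
  segs <- list(a = 1:5, b = 6:10)
  r <- fake_slab_result(c(seq(100, 60, by = -10), rep(50, 5)),
                        segments = segs)
  expect_equal(mean_normalized_dose(r, "a"), mean(c(100, 90, 80, 70, 60)))
  expect_equal(mean_normalized_dose(r, 1), 100)  # max-dose slice alone
  expect_equal(segment_attenuation(r, "a"), 40)
  expect_equal(segment_attenuation(r, "b"), 0)   # uniform segment
  expect_error(segment_attenuation(r, 3), "at least 2")
  expect_error(mean_normalized_dose(r, "zz"), "unknown segment")
})

test_that("tissue-to-air factor is 1 for air against itself", {
  s <- test_spectrum()
  air <- homogeneous_phantom("air")
  cfg <- transport_config(1e5, seed = 3, kerma_tracklength = TRUE)
  r <- transport(air, s, cfg)
  expect_equal(tissue_to_air_factor(r, r, 1:70)$value, 1)
  short <- transport(homogeneous_phantom("air", 35), s, cfg)
  expect_error(tissue_to_air_factor(r, short, 1:35), "geometry mismatch")
})

test_that("transport rejects invalid configurations", {
  expect_error(transport_config(n_histories = 0), "n_histories")
  expect_error(transport_config(electron_cut_keV = 0), "cut")
  s <- test_spectrum()
  expect_error(transport(list(), s), "phantom must be")
})

test_that("a delta-function electron histogram yields that single peak and path", {
  eh <- matrix(0, nrow = 2000, ncol = 1, dimnames = list(NULL, "water"))
  e <- (seq_len(2000) - 0.5) * 0.05
  i <- which.min(abs(e - 30))
  eh[i, 1] <- 1000
  r <- fake_slab_result(rep(1, 10), energy_hist = eh)
  pk <- electron_spectrum_peaks(r, "water", prominence = 2)
  expect_equal(pk, e[i])
  # CSDA range of a 30 keV electron in water
  m <- get_material("water")
  expect_equal(electron_path_modes(r, "water"),
               kvdosim:::kv_csda_range(e[i], m) / m$density * 1e4,
               tolerance = 0.05)
})

test_that("CSDA path scales inversely with density", {
  m1 <- kv_material("w1", 1, c(H = 0.111898, O = 0.888102))
  m2 <- kv_material("w2", 2, c(H = 0.111898, O = 0.888102))
  r1 <- kvdosim:::kv_csda_range(30, m1) / m1$density
  r2 <- kvdosim:::kv_csda_range(30, m2) / m2$density
  expect_equal(r1 / r2, 2)
})

test_that("voxel and slab transport agree on a homogeneous block", {
  s <- test_spectrum()
  # 1 mm cube voxels, 7 mm of soft tissue: z-profile must match the slab
  grid <- array(1L, dim = c(10, 10, 14))
  vox <- voxel_phantom(grid, 0.5, "soft_tissue")
  rv <- transport(vox, s, transport_config(2e5, seed = 9))
  slab <- slab_phantom(rep("soft_tissue", 14), slice_mm = 0.5,
                       lateral_mm = c(5, 5))
  rs <- transport(slab, s, transport_config(2e5, seed = 10))
  # compare depth-dose shape (normalized), voxel doses averaged per layer
  vz <- apply(array(rv$cell_dose, dim(grid)), 3, mean)
  vz <- vz / vz[1]
  sz <- rs$cell_dose / rs$cell_dose[1]
  expect_equal(vz, sz, tolerance = 0.05)
})
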