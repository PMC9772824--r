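test_that("tube spectrum respects the Duane-Hunt limit and parameter bounds", {
  s <- tube_spectrum(80)
  expect_equal(max(s$edges), 80)
  expect_true(all(s$fluence >= 0))
  expect_gt(sum(s$fluence), 0)
  expect_error(tube_spectrum(20), "kvp")
  expect_error(tube_spectrum(80, anode_angle = 50), "anode_angle")
})

test_that("tungsten K lines appear only above the K edge", {
  s60a <- tube_spectrum(60, kline_fraction = 0.05)
  s60b <- tube_spectrum(60, kline_fraction = 0)
  expect_equal(s60a$fluence, s60b$fluence)  # no lines below 69.5 kVp
  s80a <- tube_spectrum(80, kline_fraction = 0.05)
  s80b <- tube_spectrum(80, kline_fraction = 0)
  i <- which.min(abs(s80a$energy - 59.25))
  expect_gt(s80a$fluence[i], s80b$fluence[i])
})

test_that("filtering follows Beer-Lambert and hardens the beam", {
  s <- test_spectrum()
  expect_equal(filter_spectrum(s, "copper", 0)$fluence, s$fluence)
  # monoenergetic halving at t = ln2/mu
  mono <- make_spectrum(40, 1000)
  t_half <- log(2) / linear_attenuation("copper", 40) * 10  # mm
  f <- filter_spectrum(mono, "copper", t_half)
  expect_equal(sum(f$fluence), 500, tolerance = 1e-9)
  # beam hardening: mean energy strictly increases with thickness
  me <- sapply(c(0, 0.05, 0.1, 0.2),
               function(t) mean_energy(filter_spectrum(s, "copper", t)))
  expect_true(all(diff(me) > 0))
  expect_error(filter_spectrum(s, "copper", -1), "non-negative")
})

test_that("air kerma is linear in fluence and reduces to a single term", {
  s <- test_spectrum()
  expect_equal(air_kerma(make_spectrum(c(30, 40), c(0, 0))), 0)
  s2 <- s; s2$fluence <- 2 * s$fluence
  expect_equal(air_kerma(s2), 2 * air_kerma(s))
  mono <- make_spectrum(40, 7)
  expect_equal(air_kerma(mono), 7 * 40 * mass_coefficient("air", 40, "en"))
})

test_that("air kerma is invariant under bin refinement", {
  k1 <- air_kerma(tube_spectrum(80, bin_width = 0.5))
  k2 <- air_kerma(tube_spectrum(80, bin_width = 0.25))
  expect_equal(k1, k2, tolerance = 0.01)
})

test_that("analytic HVL has the monoenergetic closed form", {
  mono <- make_spectrum(40, 1)
  h <- hvl_analytic(mono, "copper")
  expect_equal(h$hvl, log(2) / linear_attenuation("copper", 40) * 10,
               tolerance = 1e-3)
})

test_that("the modelled 80 kV beam has the measured beam quality", {
  h <- hvl_analytic(test_spectrum(), "copper")
  expect_gt(h$hvl, 0.12)
  expect_lt(h$hvl, 0.15)
})

test_that("extra filtration and second layers reflect beam hardening", {
  s <- test_spectrum()
  h1 <- hvl_analytic(s)$hvl
  h1b <- hvl_analytic(filter_spectrum(s, "copper", 0.1))$hvl
  expect_gt(h1b, h1)  # pre-hardened beam has larger HVL
  # second HVL >= first
  quarter <- hvl_analytic(s, fraction = 0.25)$hvl
  expect_gte(quarter - h1, h1 * (1 - 1e-6))
})

test_that("transmission-fit HVL recovers an exact exponential", {
  mu <- 5  # 1/mm
  th <- c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  h <- hvl_from_transmission(th, exp(-mu * th))
  expect_equal(h$hvl, log(2) / mu, tolerance = 0.02)
  expect_error(hvl_from_transmission(c(0, 0.1), c(1, 0.5)), "at least 3")
  expect_error(hvl_from_transmission(c(0.1, 0.2, 0.3), c(1, 0.9, 0.8)),
               "zero thickness")
  expect_error(hvl_from_transmission(c(0, 0.1, 0.2), c(1, 1.2, 0.8)),
               "non-increasing")
})

test_that("spectrum CSV round-trips", {
  s <- test_spectrum()
  path <- tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$energy, s$energy)
  expect_equal(s2$fluence, s$fluence)
  unlink(path)
})
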