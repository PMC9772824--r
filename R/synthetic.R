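#' Seeded synthetic-data generators
#'
#' Generators for every input the analysis pipeline consumes: EPR cohorts,
#' additive-dose series (optionally with raw first-derivative curves),
#' noisy film profiles, and the voxelized leg phantom
#' ([build_leg_voxel_phantom()]).  All noise is multiplicative normal,
#' truncated at 4 sigma so that generated doses stay positive, and every
#' generator is deterministic given its seed.
#'
#' @name synthetic-data
NULL

# truncated standard normal deviates (+- 4 sigma)
kv_rtnorm <- function(n, cv) {
  if (cv == 0) return(rep(0, n))
  x <- rnorm(n)
  while (any(bad <- abs(x) > 4)) x[bad] <- rnorm(sum(bad))
  x * cv
}

#' Simulate an EPR bone-dose cohort
#'
#' Nested multiplicative model: each animal carries a latent dose
#' `k_air * true_cf * (1 + inter-animal deviate)`; each side multiplies in
#' an intra-animal deviate; the reported dose adds measurement noise and
#' carries a per-sample sigma.  Sides are dropped as missing (broken
#' sample) with the stated probability.
#'
#' @param n_mice number of animals (default 15).
#' @param k_air_Gy delivered air kerma (default 30 Gy).
#' @param true_cf true bone-to-air conversion factor (default 6.5).
#' @param inter_mouse_cv inter-animal CV (default 0.13).
#' @param intra_mouse_cv intra-animal (side) CV (default 0.08).
#' @param measurement_cv per-measurement CV (default 0.05).
#' @param missing_probability probability a side is lost (default 1/30).
#' @param seed RNG seed.
#' @return a `kv_cohort`.
#' @examples
#' cohort_statistics(simulate_cohort(seed = 1))
#' @export
simulate_cohort <- function(n_mice = 15, k_air_Gy = 30, true_cf = 6.5,
                            inter_mouse_cv = 0.13, intra_mouse_cv = 0.08,
                            measurement_cv = 0.05,
                            missing_probability = 1 / 30, seed = 1) {
  stopifnot(n_mice >= 2, inter_mouse_cv >= 0, inter_mouse_cv < 1,
            intra_mouse_cv >= 0, intra_mouse_cv < 1,
            measurement_cv >= 0, measurement_cv < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sprintf("Mouse_%02d", seq_len(n_mice))
  latent <- k_air_Gy * true_cf * (1 + kv_rtnorm(n_mice, inter_mouse_cv))
  rows <- list()
  for (i in seq_len(n_mice)) {
    for (s in c("right", "left")) {
      side_dose <- latent[i] * (1 + kv_rtnorm(1, intra_mouse_cv))
      reported <- side_dose * (1 + kv_rtnorm(1, measurement_cv))
      rel_sig <- runif(1, 0.022, 0.102)
      miss <- runif(1) < missing_probability
      rows[[length(rows) + 1]] <- data.frame(
        mouse_id = ids[i], side = s,
        dose_Gy = if (miss) NA_real_ else reported,
        sigma_Gy = if (miss) NA_real_ else reported * rel_sig,
        missing = miss)
    }
  }
  cohort_table(do.call(rbind, rows))
}

#' Simulate an additive-dose EPR series
#'
#' Replicate amplitudes `sensitivity * (d0 + added_dose) * (1 + noise)`;
#' in raw-curve mode, first-derivative lineshapes (a small low-field dip,
#' the main positive lobe and the main negative lobe over the 334--337 mT
#' scan window) are synthesized so that the first-to-third-extremum
#' peak-to-peak amplitude equals each replicate amplitude.
#'
#' @param d0_Gy true initial dose (default 194).
#' @param sensitivity signal per Gy (default 1).
#' @param added_doses_Gy added-dose schedule (default 0/50/100/150/200).
#' @param replicates measurements per dose level (3--5, default 4).
#' @param replicate_noise_cv relative replicate noise (default 0.03).
#' @param baseline_noise raw-curve baseline noise, relative to the main
#'   lobe (default 0.01).
#' @param seed RNG seed.
#' @param raw_curves also return synthetic first-derivative curves.
#' @return a `kv_additive_series`; with `raw_curves = TRUE`, a list with
#'   elements `series` and `curves` (one data.frame `field_mT`/`signal`
#'   per measurement, with the intended amplitude as attribute).
#' @examples
#' fit_additive_dose(simulate_epr_series(seed = 2))
#' @export
simulate_epr_series <- function(d0_Gy = 194, sensitivity = 1,
                                added_doses_Gy = c(0, 50, 100, 150, 200),
                                replicates = 4, replicate_noise_cv = 0.03,
                                baseline_noise = 0.01, seed = 1,
                                raw_curves = FALSE) {
  stopifnot(sensitivity > 0, replicate_noise_cv >= 0,
            replicates >= 1, replicates <= 10)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dd <- rep(added_doses_Gy, each = replicates)
  amp <- sensitivity * (d0_Gy + dd) *
    (1 + kv_rtnorm(length(dd), replicate_noise_cv))
  series <- additive_dose_series("synthetic", dd, amp)
  if (!raw_curves) return(series)
  field <- seq(334, 337, by = 0.005)
  g <- function(b0, w) exp(-(field - b0)^2 / (2 * w^2))
  curves <- lapply(amp, function(a) {
    # extrema by field: dip -0.2A, main lobe +0.8A, main trough -1.2A
    s <- a * (-0.2 * g(334.5, 0.12) + 0.8 * g(335.5, 0.12) -
                1.2 * g(336.5, 0.12))
    s <- s + rnorm(length(field), 0, baseline_noise * a)
    structure(data.frame(field_mT = field, signal = s), amplitude = a)
  })
  list(series = series, curves = curves)
}

#' Add scanner noise to a dose profile
#'
#' Multiplicative per-bin noise, then renormalization to max = 100.
#'
#' @param profile a `kv_profile`.
#' @param noise_cv relative noise per 1 mm bin.
#' @param seed RNG seed.
#' @return a noisy `kv_profile`.
#' @export
simulate_film_profile <- function(profile, noise_cv = 0.02, seed = 1) {
  stopifnot(noise_cv >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dose <- profile$dose_pct * (1 + kv_rtnorm(nrow(profile), noise_cv))
  dose <- pmax(dose, 0)
  dose <- 100 * dose / max(dose)
  out <- profile
  out$dose_pct <- dose
  out
}
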