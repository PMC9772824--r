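#' Parametric virtual source
#'
#' Gaussian focal spot plus a divergence cone, standing in for the full
#' tube-and-collimator geometry.
#'
#' @param focal_fwhm_mm focal spot FWHM in mm (default 2.3).
#' @param divergence_deg cone half-angle in degrees, in (0, 20].
#' @param position_mm source position on the beam axis (anode plane).
#' @return a `kv_virtual_source`.
#' @export
virtual_source <- function(focal_fwhm_mm = 2.3, divergence_deg = 10,
                           position_mm = 0) {
  if (focal_fwhm_mm <= 0) stop("focal FWHM must be positive")
  if (divergence_deg <= 0 || divergence_deg > 20)
    stop("divergence half-angle must lie in (0, 20] degrees")
  structure(list(focal_fwhm_mm = focal_fwhm_mm,
                 divergence_deg = divergence_deg,
                 position_mm = position_mm), class = "kv_virtual_source")
}

#' Simulate a lateral dose profile by ray tracing
#'
#' Rays start from the Gaussian focal spot, are drawn uniformly (in solid
#' angle) inside the divergence cone, pass an opaque square aperture, and
#' are scored on a 1 mm grid at the source-to-surface distance.  The
#' default aperture geometry is calibrated once so that the 50 percent
#' field edge of a point source lands at +-21.5 mm at SSD 225 mm (the
#' nominal 4.3 x 4.3 cm field).
#'
#' @param source a `kv_virtual_source`.
#' @param aperture_mm square aperture side length.
#' @param aperture_distance_mm aperture distance from the source (must be
#'   smaller than `ssd_mm`).
#' @param ssd_mm source-to-scoring-plane distance (default 225).
#' @param n_rays number of rays.
#' @param seed RNG seed.
#' @param bin_mm scoring bin width (default 1).
#' @param strip_mm half-width of the transverse strip used for the 1-d
#'   profile (default 5).
#' @return a `kv_profile`: data.frame with `position_mm`, `dose_pct`
#'   (max = 100), plus attributes.
#' @examples
#' \donttest{
#' p <- simulate_profile(n_rays = 2e5, seed = 1)
#' profile_metrics(p)
#' }
#' @export
simulate_profile <- function(source = virtual_source(),
                             aperture_mm = 43 * 145 / 225,
                             aperture_distance_mm = 145, ssd_mm = 225,
                             n_rays = 2e5, seed = 1, bin_mm = 1,
                             strip_mm = 5) {
  stopifnot(inherits(source, "kv_virtual_source"))
  if (aperture_distance_mm >= ssd_mm)
    stop("aperture must be upstream of the scoring plane")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sigma <- source$focal_fwhm_mm / (2 * sqrt(2 * log(2)))
  n <- as.integer(n_rays)
  x0 <- rnorm(n, 0, sigma)
  y0 <- rnorm(n, 0, sigma)
  cmin <- cos(source$divergence_deg * pi / 180)
  ct <- 1 - runif(n) * (1 - cmin)
  tanth <- sqrt(1 - ct^2) / ct
  phi <- runif(n, 0, 2 * pi)
  ux <- tanth * cos(phi)
  uy <- tanth * sin(phi)
  xa <- x0 + ux * aperture_distance_mm
  ya <- y0 + uy * aperture_distance_mm
  half <- aperture_mm / 2
  ok <- abs(xa) <= half & abs(ya) <= half
  xs <- x0[ok] + ux[ok] * ssd_mm
  ys <- y0[ok] + uy[ok] * ssd_mm
  strip <- abs(ys) <= strip_mm
  xs <- xs[strip]
  lim <- ceiling(max(35, max(abs(xs)))) + 2
  breaks <- seq(-lim, lim, by = bin_mm)
  cnt <- hist(xs, breaks = breaks, plot = FALSE)$counts
  pos <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dose <- 100 * cnt / max(cnt)
  structure(data.frame(position_mm = pos, dose_pct = dose),
            class = c("kv_profile", "data.frame"),
            axis = "x", ssd_mm = ssd_mm, n_rays = n_rays, seed = seed)
}

# save/restore R's RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

kv_level_crossings <- function(pos, dose, level) {
  # leftmost and rightmost crossings of `level` by linear interpolation
  above <- dose >= level
  if (!any(above)) return(NULL)
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  left <- if (i1 == 1) pos[1] else {
    f <- (level - dose[i1 - 1]) / (dose[i1] - dose[i1 - 1])
    pos[i1 - 1] + f * (pos[i1] - pos[i1 - 1])
  }
  right <- if (i2 == length(pos)) pos[i2] else {
    f <- (level - dose[i2 + 1]) / (dose[i2] - dose[i2 + 1])
    pos[i2 + 1] + f * (pos[i2] - pos[i2 + 1])
  }
  c(left, right)
}

#' Profile width and penumbra metrics
#'
#' FWHM by linear interpolation at the 50 percent level; beam fringe
#' (penumbra) as the lateral distance between the 80 and 20 percent levels
#' on each side.
#'
#' @param profile a `kv_profile` (or data.frame with `position_mm`,
#'   `dose_pct`).
#' @return list with `fwhm_mm`, `fringe_left_mm`, `fringe_right_mm`.
#' @export
profile_metrics <- function(profile) {
  pos <- profile$position_mm
  dose <- profile$dose_pct
  c50 <- kv_level_crossings(pos, dose, 50)
  if (is.null(c50)) stop("profile never reaches the 50% level")
  c80 <- kv_level_crossings(pos, dose, 80)
  c20 <- kv_level_crossings(pos, dose, 20)
  if (is.null(c80) || is.null(c20))
    stop("profile lacks an 80%/20% penumbra region")
  list(fwhm_mm = c50[2] - c50[1],
       fringe_left_mm = c80[1] - c20[1],
       fringe_right_mm = c20[2] - c80[2])
}

#' IAEA-style comparison of two dose profiles
#'
#' The simulated profile is resampled onto the measured position grid by
#' linear interpolation; deviations are reported for the FWHM, the fringes,
#' the central/build-up region (points at or above 90 percent of the
#' maximum; absolute deviation in percentage points) and the region outside
#' the beam edge (points below 20 percent; relative deviation), with
#' pass/fail flags at the 2 and 30 percent thresholds.
#'
#' @param measured,simulated `kv_profile`s on overlapping position grids.
#' @param central_threshold_pct pass threshold for the central region.
#' @param outside_threshold_pct pass threshold outside the beam edge.
#' @return list of deviations and pass flags.
#' @export
iaea_compare <- function(measured, simulated, central_threshold_pct = 2,
                         outside_threshold_pct = 30) {
  pm <- measured$position_mm
  if (length(pm) == 0 || length(simulated$position_mm) == 0)
    stop("profiles do not overlap")
  keep <- pm >= min(simulated$position_mm) & pm <= max(simulated$position_mm)
  if (!any(keep)) stop("profiles do not overlap")
  pm <- pm[keep]
  dm <- measured$dose_pct[keep]
  ds <- approx(simulated$position_mm, simulated$dose_pct, xout = pm)$y
  mm <- profile_metrics(measured)
  ms <- profile_metrics(simulated)
  fwhm_dev <- ms$fwhm_mm - mm$fwhm_mm
  central <- dm >= 90
  outside <- dm < 20 & dm > 0.5
  central_dev <- if (any(central)) max(abs(ds[central] - dm[central])) else NA
  outside_dev <- if (any(outside))
    max(abs(ds[outside] - dm[outside]) / dm[outside]) * 100 else 0
  list(fwhm_deviation_mm = fwhm_dev,
       fwhm_deviation_pct = 100 * abs(fwhm_dev) / mm$fwhm_mm,
       fringe_left_deviation_mm = ms$fringe_left_mm - mm$fringe_left_mm,
       fringe_right_deviation_mm = ms$fringe_right_mm - mm$fringe_right_mm,
       central_max_deviation_pct = central_dev,
       outside_max_relative_deviation_pct = outside_dev,
       pass_central = is.finite(central_dev) &&
         central_dev <= central_threshold_pct,
       pass_outside = outside_dev <= outside_threshold_pct)
}

#' Radiochromic film calibration
#'
#' Least-squares fourth-degree polynomial fit of net film response against
#' dose; dose read-out inverts the fitted curve by root finding within the
#' calibrated range.
#'
#' @param dose_Gy calibration doses (>= 6 points spanning the range,
#'   including low dose).
#' @param response net film responses (monotonically increasing with dose).
#' @return a `kv_film_calibration`; use [film_dose()] to convert responses.
#' @examples
#' d <- seq(0, 3, by = 0.5)
#' cal <- film_calibration(d, 0.1 * d + 0.02 * d^2)
#' film_dose(cal, 0.2)
#' @export
film_calibration <- function(dose_Gy, response) {
  if (length(dose_Gy) < 6) stop("need at least 6 calibration points")
  if (length(response) != length(dose_Gy)) stop("length mismatch")
  o <- order(dose_Gy)
  dose_Gy <- dose_Gy[o]; response <- response[o]
  fit <- lm(response ~ poly(dose_Gy, 4, raw = TRUE))
  grid <- seq(min(dose_Gy), max(dose_Gy), length.out = 400)
  pred <- predict(fit, newdata = data.frame(dose_Gy = grid))
  if (any(diff(pred) <= 0))
    stop("fitted calibration is not monotone over the calibrated range")
  structure(list(fit = fit, dose_range = range(dose_Gy),
                 response_range = range(pred)), class = "kv_film_calibration")
}

#' @param cal a `kv_film_calibration`.
#' @param new_response net response(s) to convert to dose.
#' @return dose(s) in Gy.
#' @rdname film_calibration
#' @export
film_dose <- function(cal, new_response) {
  stopifnot(inherits(cal, "kv_film_calibration"))
  vapply(new_response, function(r) {
    if (r < cal$response_range[1] - 1e-9 || r > cal$response_range[2] + 1e-9)
      stop("response outside the calibrated range")
    f <- function(d) predict(cal$fit, newdata = data.frame(dose_Gy = d)) - r
    flo <- f(cal$dose_range[1]); fhi <- f(cal$dose_range[2])
    if (flo >= 0) return(cal$dose_range[1])  # monotone: at/below low end
    if (fhi <= 0) return(cal$dose_range[2])
    uniroot(f, interval = cal$dose_range, extendInt = "no",
            tol = 1e-10)$root
  }, 0)
}
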