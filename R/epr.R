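#' Peak-to-peak amplitude of a first-derivative EPR curve
#'
#' Signal difference between the first and third local extrema of the
#' recorded first-derivative spectrum, extrema ordered by magnetic field.
#' Extrema smaller than `min_height` times the absolute maximum are treated
#' as baseline noise.
#'
#' @param field_mT magnetic field values (ascending).
#' @param signal first-derivative signal.
#' @param min_height relative threshold for counting an extremum.
#' @return peak-to-peak amplitude (same units as `signal`).
#' @export
peak_to_peak <- function(field_mT, signal, min_height = 0.05) {
  stopifnot(length(field_mT) == length(signal))
  if (is.unsorted(field_mT)) {
    o <- order(field_mT)
    field_mT <- field_mT[o]; signal <- signal[o]
  }
  n <- length(signal)
  # light smoothing against scanner/baseline noise
  k <- max(3L, round(n / 100))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::filter(signal, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- signal[is.na(sm)]
  rng <- max(sm) - min(sm)
  if (rng == 0) stop("flat curve: no extrema")
  thr <- min_height * rng
  d <- diff(sm)
  ext <- integer(0); typ <- integer(0)  # +1 max, -1 min
  for (i in 2:(n - 1)) {
    t <- if (d[i - 1] > 0 && d[i] <= 0) 1L
         else if (d[i - 1] < 0 && d[i] >= 0) -1L else 0L
    if (t == 0L) next
    if (length(ext) && t == typ[length(typ)]) {
      # same-type run: keep the more extreme one
      if ((t == 1L && sm[i] > sm[ext[length(ext)]]) ||
          (t == -1L && sm[i] < sm[ext[length(ext)]])) {
        ext[length(ext)] <- i
      }
    } else if (!length(ext) || abs(sm[i] - sm[ext[length(ext)]]) >= thr) {
      ext <- c(ext, i); typ <- c(typ, t)
    }
  }
  keep <- abs(sm[ext]) >= min_height * max(abs(sm))
  ext <- ext[keep]; typ <- typ[keep]
  if (length(ext) < 3) stop("fewer than 3 extrema in the EPR curve")
  # refine extremum values by a local quadratic fit on the raw curve
  # (noise-averaged, and free of the boxcar's peak-flattening bias)
  val <- function(j) {
    w <- max(1, ext[j] - 2 * k):min(n, ext[j] + 2 * k)
    x <- field_mT[w] - field_mT[ext[j]]
    cf <- coef(lm(signal[w] ~ x + I(x^2)))
    if (abs(cf[3]) < 1e-12) return(sm[ext[j]])
    unname(cf[1] - cf[2]^2 / (4 * cf[3]))
  }
  abs(val(1) - val(3))
}

#' Additive-dose series
#'
#' Container for an additive-dose EPR experiment on one bone sample:
#' replicate peak-to-peak amplitudes measured after re-irradiation with
#' known added doses (the first added dose must be 0).
#'
#' @param sample_id sample identifier.
#' @param added_dose_Gy added dose for each measurement (>= 3 distinct
#'   values, first level 0, strictly increasing levels).
#' @param amplitude peak-to-peak amplitude for each measurement.
#' @param replicate optional replicate index per measurement.
#' @return a `kv_additive_series` (data.frame).
#' @export
additive_dose_series <- function(sample_id, added_dose_Gy, amplitude,
                                 replicate = NULL) {
  stopifnot(length(added_dose_Gy) == length(amplitude))
  lev <- sort(unique(added_dose_Gy))
  if (length(lev) < 3) stop("need at least 3 distinct added doses")
  if (lev[1] != 0) stop("the first added dose must be 0")
  if (any(lev < 0)) stop("added doses must be non-negative")
  reps <- table(added_dose_Gy)
  if (any(reps < 1) || any(reps > 10))
    stop("replicate counts must lie in [1, 10]")
  if (is.null(replicate))
    replicate <- stats::ave(added_dose_Gy, added_dose_Gy,
                            FUN = seq_along)
  structure(data.frame(sample_id = sample_id,
                       added_dose_Gy = added_dose_Gy,
                       replicate = replicate, amplitude = amplitude),
            class = c("kv_additive_series", "data.frame"))
}

#' Additive-dose fit: reconstructed initial dose
#'
#' Ordinary least squares of amplitude against added dose (replicate means
#' by default).  The initial dose is the ratio of intercept to slope, i.e.
#' the magnitude of the extrapolated zero-signal dose; its uncertainty
#' follows from first-order propagation of the parameter covariance:
#' \deqn{\sigma^2 = d_0^2\left[(\sigma_a/a)^2 + (\sigma_b/b)^2 -
#'   2\,\mathrm{cov}(a,b)/(ab)\right].}
#'
#' With replicate means, the parameter covariance uses the pooled
#' within-dose variance of the mean (measurement-derived, as the replicate
#' scatter is the dominant uncertainty source); with
#' `use_replicates = TRUE` all points enter the fit individually and the
#' usual residual-based covariance is used.
#'
#' @param series a `kv_additive_series`.
#' @param use_replicates fit all replicate points instead of dose-level
#'   means.
#' @return a `kv_dose_estimate`: list with `d0_Gy`, `sigma_Gy`, `slope`,
#'   `intercept`, `covariance`.
#' @export
fit_additive_dose <- function(series, use_replicates = FALSE) {
  stopifnot(inherits(series, "kv_additive_series"))
  if (use_replicates) {
    x <- series$added_dose_Gy
    y <- series$amplitude
    fit <- lm(y ~ x)
    V <- vcov(fit)
  } else {
    means <- tapply(series$amplitude, series$added_dose_Gy, mean)
    x <- as.numeric(names(means))
    y <- as.numeric(means)
    fit <- lm(y ~ x)
    m_i <- tapply(series$amplitude, series$added_dose_Gy, length)
    v_i <- tapply(series$amplitude, series$added_dose_Gy, var)
    v_i[is.na(v_i)] <- 0
    s2 <- mean(v_i / m_i)          # pooled variance of a dose-level mean
    X <- cbind(1, x)
    V <- if (s2 > 0) s2 * solve(crossprod(X)) else matrix(0, 2, 2)
  }
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  if (!is.finite(b) || b <= 0)
    stop("non-positive slope: sample shows no radiation response")
  d0 <- a / b
  s2d <- d0^2 * (V[1, 1] / a^2 + V[2, 2] / b^2 - 2 * V[1, 2] / (a * b))
  structure(list(d0_Gy = d0, sigma_Gy = sqrt(max(s2d, 0)), slope = b,
                 intercept = a, covariance = V),
            class = "kv_dose_estimate")
}

#' @export
print.kv_dose_estimate <- function(x, ...) {
  cat("<kv_dose_estimate> d0 = ", round(x$d0_Gy, 1), " +- ",
      round(x$sigma_Gy, 1), " Gy\n", sep = "")
  invisible(x)
}

#' Cohort table of per-animal left/right bone doses
#'
#' @param df data.frame with columns `mouse_id`, `side` (`left`/`right`),
#'   `dose_Gy`, `sigma_Gy`, `missing` (logical; missing rows carry no
#'   dose).
#' @return a `kv_cohort` (validated data.frame).
#' @export
cohort_table <- function(df) {
  need <- c("mouse_id", "side", "dose_Gy", "sigma_Gy", "missing")
  if (!all(need %in% names(df)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  if (anyDuplicated(df[, c("mouse_id", "side")]))
    stop("at most one row per (mouse, side)")
  if (any(!df$missing & !is.finite(df$dose_Gy)))
    stop("non-missing rows must carry a dose")
  df$dose_Gy[df$missing] <- NA_real_
  df$sigma_Gy[df$missing] <- NA_real_
  structure(df, class = c("kv_cohort", "data.frame"))
}

#' @param path CSV file with the cohort-table columns.
#' @rdname cohort_table
#' @export
read_cohort <- function(path) {
  cohort_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Packaged EPR cohort of bone doses
#'
#' The 15-mouse, left/right tibia bone-dose cohort measured by additive-dose
#' EPR spectroscopy after 30 Gy air-kerma irradiation at 80 kV (one left
#' tibia broken during preparation and excluded).
#'
#' @return a `kv_cohort`.
#' @export
bone_dose_cohort <- function() {
  read_cohort(system.file("extdata", "epr_cohort_doses.csv",
                          package = "kvdosim", mustWork = TRUE))
}

#' Cohort variability statistics
#'
#' Per-side and combined mean, SD (divisor n-1) and coefficient of
#' variation of the non-missing doses; the per-mouse pair CV
#' \eqn{(|L-R|/\sqrt{2}) / \mathrm{mean}(L,R)} for animals with both sides
#' present (the intra-animal variability); and a moment-based estimate of
#' the inter-animal CV obtained by subtracting half the mean squared pair
#' CV from the squared CV of the per-mouse means.
#'
#' @param cohort a `kv_cohort`.
#' @return a `kv_cohort_stats` list.
#' @examples
#' cohort_statistics(bone_dose_cohort())
#' @export
cohort_statistics <- function(cohort) {
  stopifnot(inherits(cohort, "kv_cohort"))
  ok <- !cohort$missing
  if (sum(ok) < 2) stop("need at least 2 non-missing doses")
  side_stats <- function(s) {
    d <- cohort$dose_Gy[ok & cohort$side == s]
    if (length(d) == 0) stop("no non-missing doses on side '", s, "'")
    c(mean = mean(d), sd = sd(d), cv_pct = 100 * sd(d) / mean(d),
      n = length(d))
  }
  right <- side_stats("right")
  left <- side_stats("left")
  d_all <- cohort$dose_Gy[ok]
  combined <- c(mean = mean(d_all), sd = sd(d_all),
                cv_pct = 100 * sd(d_all) / mean(d_all), n = length(d_all))
  # intra-animal pair CVs
  wide <- merge(
    cohort[ok & cohort$side == "left", c("mouse_id", "dose_Gy")],
    cohort[ok & cohort$side == "right", c("mouse_id", "dose_Gy")],
    by = "mouse_id", suffixes = c("_L", "_R"))
  pair_cv <- 100 * (abs(wide$dose_Gy_L - wide$dose_Gy_R) / sqrt(2)) /
    ((wide$dose_Gy_L + wide$dose_Gy_R) / 2)
  mouse_means <- (wide$dose_Gy_L + wide$dose_Gy_R) / 2
  cv_means <- sd(mouse_means) / mean(mouse_means)
  inter_cv <- sqrt(max(cv_means^2 - mean((pair_cv / 100)^2) / 2, 0))
  structure(list(right = right, left = left, combined = combined,
                 pair_cv_pct = setNames(pair_cv, wide$mouse_id),
                 mean_pair_cv_pct = mean(pair_cv),
                 pair_cv_range_pct = range(pair_cv),
                 inter_mouse_cv_pct = 100 * inter_cv),
            class = "kv_cohort_stats")
}

#' @export
print.kv_cohort_stats <- function(x, ...) {
  f <- function(v) sprintf("%.1f +- %.1f Gy (CV %.1f%%, n=%d)",
                           v["mean"], v["sd"], v["cv_pct"], v["n"])
  cat("<kv_cohort_stats>\n")
  cat("  right:   ", f(x$right), "\n")
  cat("  left:    ", f(x$left), "\n")
  cat("  combined:", f(x$combined), "\n")
  cat(sprintf("  intra-animal pair CV: %.1f%% (range %.1f-%.1f%%)\n",
              x$mean_pair_cv_pct, x$pair_cv_range_pct[1],
              x$pair_cv_range_pct[2]))
  invisible(x)
}

#' Bone-to-air-kerma conversion factors of a cohort
#'
#' Mean bone dose divided by the delivered air kerma (treated as exact);
#' the quoted sigma is the cohort SD divided by the air kerma.
#'
#' @param stats a `kv_cohort_stats`.
#' @param k_air_Gy delivered air kerma in Gy (default 30).
#' @return data.frame with rows right/left/combined and columns `value`,
#'   `sigma`.
#' @examples
#' cohort_conversion_factor(cohort_statistics(bone_dose_cohort()))
#' @export
cohort_conversion_factor <- function(stats, k_air_Gy = 30) {
  stopifnot(inherits(stats, "kv_cohort_stats"))
  if (k_air_Gy <= 0) stop("air kerma must be positive")
  rows <- list(right = stats$right, left = stats$left,
               combined = stats$combined)
  data.frame(group = names(rows),
             value = vapply(rows, function(v) v[["mean"]] / k_air_Gy, 0),
             sigma = vapply(rows, function(v) v[["sd"]] / k_air_Gy, 0),
             row.names = NULL)
}
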