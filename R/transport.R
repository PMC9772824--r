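#' Transport configuration
#'
#' @param n_histories number of primary photon histories (>= 1).
#' @param seed integer seed; a fixed seed gives bit-identical results.
#' @param electron_cut_keV electrons below this energy deposit locally
#'   (default 0.25 keV).
#' @param rayleigh include Rayleigh scattering (direction-only).
#' @param fluorescence track K-alpha fluorescence photons (otherwise their
#'   energy deposits locally).
#' @param local_deposition deposit all secondary-electron energy at the
#'   creation site (collision-kerma scoring; used for free-in-air
#'   reference runs where charged-particle equilibrium is not established).
#' @param photoelectric_only restrict interactions to the photoelectric
#'   channel (analytic-oracle mode: depth dose follows exp(-mu_pe z)).
#' @param kerma_tracklength score collision kerma with a track-length
#'   estimator instead of analog energy deposition (low-variance mode for
#'   free-in-air reference runs; the energy-balance record is not
#'   meaningful in this mode).
#' @param window_mm beam window `c(x, y)` in mm; `NULL` covers the phantom.
#' @param n_batches number of statistical batches for error estimation.
#' @return a `kv_transport_config`.
#' @export
transport_config <- function(n_histories = 1e6, seed = 1,
                             electron_cut_keV = 0.25, rayleigh = TRUE,
                             fluorescence = TRUE, local_deposition = FALSE,
                             photoelectric_only = FALSE,
                             kerma_tracklength = FALSE, window_mm = NULL,
                             n_batches = 25) {
  if (n_histories < 1) stop("n_histories must be >= 1")
  if (electron_cut_keV <= 0) stop("electron cut must be positive")
  structure(list(n_histories = n_histories, seed = seed,
                 electron_cut_keV = electron_cut_keV, rayleigh = rayleigh,
                 fluorescence = fluorescence,
                 local_deposition = local_deposition,
                 photoelectric_only = photoelectric_only,
                 kerma_tracklength = kerma_tracklength,
                 window_mm = window_mm, n_batches = n_batches),
            class = "kv_transport_config")
}

# linear coefficient tables (1/mm) for one material on the union grid of
# its elements, plus per-element photoelectric shares for relaxation
kv_mat_tables <- function(name) {
  m <- get_material(name)
  tabs <- kv_tables()$coeff
  grid <- sort(unique(unlist(lapply(names(m$fractions), function(el)
    tabs[[el]]$energy_keV))))
  lin <- function(kind) {
    list(energy = grid,
         value = mass_coefficient(m, grid, kind) * m$density / 10)
  }
  rel <- kv_tables()$relax
  relax <- list()
  for (el in names(m$fractions)) {
    r <- rel[el, ]
    if (r$K_edge_keV > 1.05 && m$fractions[[el]] > 0) {
      relax[[el]] <- list(
        k_edge = r$K_edge_keV, omega = r$K_fluorescence_yield,
        kalpha = r$K_alpha_keV, auger = r$KLL_auger_keV,
        pK = r$K_shell_fraction,
        mu_pe = list(energy = grid,
                     value = m$fractions[[el]] *
                       .kv_interp_element(el, grid, "photoelectric") *
                       m$density / 10))
    }
  }
  zoa_w <- 0.111898 * 1 / 1.008 + 0.888102 * 8 / 15.999
  list(rho = m$density, zoa_scale = zoa_w / kv_zoa(m),
       mu_total = lin("total"), mu_pe = lin("photoelectric"),
       mu_compton = lin("compton"), mu_rayleigh = lin("rayleigh"),
       mu_en = lin("en"),
       relax = unname(relax))
}

#' Monte Carlo photon/electron transport in a phantom
#'
#' Photons enter along +z, uniformly over the beam window, with energies
#' sampled from the supplied spectrum.  See the package vignette for the
#' physics model.
#'
#' @param phantom a `kv_slab_phantom` or `kv_voxel_phantom`.
#' @param spectrum a `kv_spectrum`.
#' @param config a `kv_transport_config`.
#' @return a `kv_transport_result`: per-slice (or per-voxel-layer) dose and
#'   statistical error, per-region dose summaries, per-material secondary
#'   electron energy and CSDA-path histograms, interaction counts, and the
#'   energy balance.
#' @examples
#' \donttest{
#' s <- tube_spectrum(80)
#' ph <- heterogeneous_leg_phantom()
#' res <- transport(ph, s, transport_config(n_histories = 1e5, seed = 7))
#' res$regions
#' }
#' @export
transport <- function(phantom, spectrum, config = transport_config()) {
  kv_check_spectrum(spectrum)
  stopifnot(inherits(config, "kv_transport_config"))
  is_slab <- inherits(phantom, "kv_slab_phantom")
  if (!is_slab && !inherits(phantom, "kv_voxel_phantom"))
    stop("phantom must be a kv_slab_phantom or kv_voxel_phantom")

  if (is_slab) {
    mat_names <- unique(phantom$slices)
    cell_mat <- match(phantom$slices, mat_names) - 1L
    nslice <- length(phantom$slices)
    dims <- c(0L, 0L, nslice)
    lateral <- as.numeric(phantom$lateral_mm)
    cell_mm <- phantom$slice_mm
    # regions: named segments (possibly overlapping -> first wins), rest 0
    segs <- phantom$segments
    region <- rep(0L, nslice)
    region_names <- "other"
    if (!is.null(segs)) {
      for (i in seq_along(segs)) {
        nm <- names(segs)[i]
        idx <- segs[[i]]
        fresh <- idx[region[idx] == 0L]
        if (length(fresh)) {
          region_names <- c(region_names, nm)
          region[fresh] <- length(region_names) - 1L
        }
      }
    }
    rho_cell <- unname(vapply(phantom$slices,
                              function(m) get_material(m)$density, 0))
    mass_cell <- rho_cell * lateral[1] * lateral[2] * cell_mm / 1000  # g
    window <- config$window_mm
    if (is.null(window)) window <- lateral
  } else {
    mat_names <- phantom$materials
    cell_mat <- as.integer(phantom$grid) - 1L
    dims <- as.integer(dim(phantom$grid))
    lateral <- c(dims[1], dims[2]) * phantom$voxel_mm
    cell_mm <- phantom$voxel_mm
    region <- cell_mat
    region_names <- mat_names
    rho <- vapply(mat_names, function(m) get_material(m)$density, 0)
    mass_cell <- rho[cell_mat + 1L] * (cell_mm / 10)^3  # g
    window <- config$window_mm
    if (is.null(window)) window <- lateral
  }

  mats <- lapply(mat_names, kv_mat_tables)
  keep <- spectrum$fluence > 0
  en <- spectrum$energy[keep]
  fl <- spectrum$fluence[keep]
  cdf <- cumsum(fl) / sum(fl)
  bw <- if (length(spectrum$edges) > 1) diff(spectrum$edges)[1] else 0

  cs <- kv_tables()$csda
  raw <- transport_cpp(
    geom_type = if (is_slab) 0L else 1L, dims = dims, cell_mm = cell_mm,
    lateral_mm = lateral, window_mm = window, cell_mat = cell_mat,
    cell_region = region, nregion = length(region_names), mats = mats,
    csda_table = list(energy = cs$energy_keV, value = cs$csda_range_g_cm2),
    spec_energy = en, spec_cdf = cdf, spec_binwidth = bw,
    n_histories = config$n_histories, seed = config$seed,
    cut_keV = config$electron_cut_keV, rayleigh = config$rayleigh,
    fluorescence = config$fluorescence,
    local_deposition = config$local_deposition,
    photoelectric_only = config$photoelectric_only,
    kerma_tracklength = config$kerma_tracklength,
    n_batches = as.integer(config$n_batches))

  nb <- config$n_batches
  cell_tot <- colSums(raw$cell_batch)
  cell_dose <- cell_tot / mass_cell / config$n_histories
  bmean <- colMeans(raw$cell_batch)
  bsd <- apply(raw$cell_batch, 2, sd)
  cell_stderr <- ifelse(cell_tot > 0, bsd * sqrt(nb) / mass_cell /
                          config$n_histories, 0)
  # region summaries (dose = total energy / total mass)
  region_mass <- as.numeric(tapply(mass_cell, factor(region,
                            levels = seq_along(region_names) - 1L), sum))
  region_mass[is.na(region_mass)] <- 0
  reg_tot <- colSums(raw$region_batch)
  reg_dose <- ifelse(region_mass > 0,
                     reg_tot / region_mass / config$n_histories, NA_real_)
  reg_sd <- apply(raw$region_batch, 2, sd) * sqrt(nb)
  reg_stderr <- ifelse(region_mass > 0,
                       reg_sd / region_mass / config$n_histories, NA_real_)
  regions <- data.frame(region = region_names, dose = reg_dose,
                        dose_stderr = reg_stderr, mass_g = region_mass)

  ne <- nrow(raw$electron_energy_hist)
  np <- nrow(raw$electron_path_hist)
  colnames(raw$electron_energy_hist) <- mat_names
  colnames(raw$electron_path_hist) <- mat_names
  rownames(raw$counts) <- c("photoelectric", "compton", "rayleigh",
                            "fluorescence", "electrons")
  colnames(raw$counts) <- mat_names

  structure(list(
    is_slab = is_slab, phantom = phantom, config = config,
    cell_dose = cell_dose, cell_dose_stderr = cell_stderr,
    depth_mm = (seq_along(cell_dose) - 0.5) * cell_mm,
    cell_region = region, region_names = region_names, regions = regions,
    electron_energy_keV = (seq_len(ne) - 0.5) * raw$ebin_keV,
    electron_energy_hist = raw$electron_energy_hist,
    electron_path_um = (seq_len(np) - 0.5) * raw$pbin_um,
    electron_path_hist = raw$electron_path_hist,
    counts = raw$counts,
    energy = c(incident = raw$energy_in, deposited = raw$energy_deposited,
               escaped = raw$energy_escaped),
    seed = config$seed), class = "kv_transport_result")
}

#' @export
print.kv_transport_result <- function(x, ...) {
  cat("<kv_transport_result> ", format(x$config$n_histories, big.mark = ","),
      " histories, seed ", x$seed, "\n", sep = "")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

kv_segment_slices <- function(result, segment) {
  if (is.numeric(segment)) return(as.integer(segment))
  if (!result$is_slab) stop("named segments require a slab result")
  segs <- result$phantom$segments
  if (is.null(segs) || !segment %in% names(segs))
    stop("unknown segment '", segment, "'")
  segs[[segment]]
}

#' Mean normalized dose of a tissue segment
#'
#' Mean slice dose over a segment, normalized so that the maximum slice
#' dose in the phantom equals 100 percent.
#'
#' @param result a slab `kv_transport_result`.
#' @param segment segment name (see [heterogeneous_leg_phantom()]) or a
#'   vector of slice indices.
#' @return percent of the maximum slice dose.
#' @export
mean_normalized_dose <- function(result, segment) {
  idx <- kv_segment_slices(result, segment)
  if (length(idx) < 1) stop("empty segment")
  100 * mean(result$cell_dose[idx]) / max(result$cell_dose)
}

#' Dose attenuation across a tissue segment
#'
#' `(first-slice dose - last-slice dose) / first-slice dose`, in percent.
#'
#' @inheritParams mean_normalized_dose
#' @export
segment_attenuation <- function(result, segment) {
  idx <- kv_segment_slices(result, segment)
  if (length(idx) < 2) stop("segment needs at least 2 slices")
  d <- result$cell_dose[idx]
  100 * (d[1] - d[length(d)]) / d[1]
}

#' Tissue-to-air conversion factor from paired transport runs
#'
#' Mean dose of a tissue segment divided by the mean dose of an identical
#' all-air reference run over the same slice indices (or, for voxel
#' phantoms, the same spatial region).
#'
#' @param result transport result for the tissue phantom.
#' @param air_result transport result for the all-air phantom of identical
#'   geometry and histories (typically run with
#'   `local_deposition = TRUE`, i.e. kerma scoring).
#' @param segment segment name, slice indices, or (voxel) region name.
#' @return a `kv_conversion_factor` with a `stderr` field.
#' @export
tissue_to_air_factor <- function(result, air_result, segment) {
  if (length(result$cell_dose) != length(air_result$cell_dose))
    stop("geometry mismatch between tissue and air runs")
  if (result$is_slab) {
    idx <- kv_segment_slices(result, segment)
    d <- mean(result$cell_dose[idx])
    a <- mean(air_result$cell_dose[idx])
    rel <- sqrt(mean(result$cell_dose_stderr[idx]^2) / d^2 +
                  mean(air_result$cell_dose_stderr[idx]^2) / a^2)
  } else {
    i <- match(segment, result$region_names)
    if (is.na(i)) stop("unknown region '", segment, "'")
    vox <- which(result$cell_region == (i - 1L))
    d <- mean(result$cell_dose[vox])
    a <- mean(air_result$cell_dose[vox])
    rel <- NA_real_
  }
  if (!is.finite(a) || a <= 0) stop("air reference dose is zero")
  structure(list(value = d / a, tissue = as.character(segment)[1],
                 reference = "air", stderr = d / a * rel),
            class = "kv_conversion_factor")
}

#' Peaks of a per-tissue secondary-electron energy spectrum
#'
#' Local maxima of the 0.05 keV-binned electron energy histogram whose
#' height exceeds the local continuum by a relative prominence threshold.
#'
#' @param result a `kv_transport_result`.
#' @param tissue material name.
#' @param prominence minimum relative excess over the local continuum
#'   (median of the surrounding +-10 bins).  The default 7 requires a line
#'   to stand roughly an order of magnitude above the continuum, which
#'   retains the K-shell relaxation lines of the bone minerals while
#'   rejecting the weak lines of sub-percent trace elements.
#' @param min_counts ignore bins with fewer counts (noise guard).
#' @return numeric vector of peak energies (keV), possibly empty.
#' @export
electron_spectrum_peaks <- function(result, tissue, prominence = 7,
                                    min_counts = 50) {
  h <- result$electron_energy_hist[, tissue]
  if (sum(h) == 0) stop("empty electron histogram for ", tissue)
  e <- result$electron_energy_keV
  peaks <- numeric(0)
  n <- length(h)
  for (i in seq(4, n - 3)) {
    if (h[i] < min_counts) next
    win <- max(1, i - 10):min(n, i + 10)
    win <- setdiff(win, (i - 2):(i + 2))
    base <- median(h[win])
    if (h[i] == max(h[max(1, i - 2):min(n, i + 2)]) &&
        h[i] > (1 + prominence) * max(base, 1)) {
      peaks <- c(peaks, e[i])
    }
  }
  # merge peaks from adjacent bins
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > 0.11)
    peaks <- peaks[keep]
  }
  peaks
}

#' Modal CSDA path length of secondary electrons in a tissue
#'
#' Modal CSDA range of the penetrating photoelectron population
#' (electrons created above `min_energy_keV`), computed from the
#' per-tissue electron energy histogram.  The K-shell relaxation lines
#' have sub-micron ranges and deposit their energy essentially on the
#' spot, and Compton recoils (below about 16 keV for an 80 kVp beam) pile
#' up at any lower threshold; the photoelectron population is common to
#' all tissues and carries dose across slice boundaries, so its modal
#' path scales with the reciprocal of the tissue density and the modes
#' order cortical < trabecular < soft tissue.
#'
#' @param result a `kv_transport_result`.
#' @param tissue material name.
#' @param min_energy_keV lower energy bound of the population (default 16,
#'   above the maximum Compton recoil energy of an 80 kVp beam).
#' @param bin_um path-histogram bin width for the mode search.
#' @return modal path length in micrometres.
#' @export
electron_path_modes <- function(result, tissue, min_energy_keV = 16,
                                bin_um = 0.05) {
  h <- result$electron_energy_hist[, tissue]
  e <- result$electron_energy_keV
  keep <- e >= min_energy_keV & h > 0
  if (!any(keep)) stop("no electrons above ", min_energy_keV, " keV in ",
                       tissue)
  m <- get_material(tissue)
  r_um <- kv_csda_range(pmin(e[keep], 100), m) / m$density * 1e4
  breaks <- seq(0, max(r_um) + bin_um, by = bin_um)
  agg <- tapply(h[keep], cut(r_um, breaks, include.lowest = TRUE), sum)
  agg[is.na(agg)] <- 0
  as.numeric(breaks[which.max(agg)] + bin_um / 2)
}

#' Interface dose ratio near cortical bone layers
#'
#' Ratio of the heterogeneous-phantom soft-tissue dose to the homogeneous
#' soft-tissue dose, slice by slice, flagging the 100 um slices adjacent
#' to each cortical layer (backscatter upstream, forward electrons
#' downstream).
#'
#' @param het_result transport result for the heterogeneous phantom.
#' @param soft_result transport result for the all-soft-tissue phantom on
#'   the identical slice grid.
#' @return data.frame with `slice`, `depth_mm`, `ratio`, `ratio_stderr` and
#'   `position` (`"upstream"`, `"downstream"` or `"bulk"`), for soft-tissue
#'   slices only.
#' @export
interface_dose_analysis <- function(het_result, soft_result) {
  if (length(het_result$cell_dose) != length(soft_result$cell_dose))
    stop("slice grids differ")
  mats <- het_result$phantom$slices
  soft <- which(mats == "soft_tissue")
  bone <- which(mats != "soft_tissue")
  ratio <- het_result$cell_dose[soft] / soft_result$cell_dose[soft]
  rel <- sqrt((het_result$cell_dose_stderr[soft] /
                 het_result$cell_dose[soft])^2 +
              (soft_result$cell_dose_stderr[soft] /
                 soft_result$cell_dose[soft])^2)
  position <- rep("bulk", length(soft))
  position[(soft + 1) %in% bone] <- "upstream"
  position[(soft - 1) %in% bone] <- "downstream"
  data.frame(slice = soft, depth_mm = het_result$depth_mm[soft],
             ratio = ratio, ratio_stderr = ratio * rel, position = position)
}
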