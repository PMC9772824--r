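#' Embedded photon interaction data
#'
#' The package ships per-element mass interaction coefficients (cm^2/g) on a
#' 1--200 keV grid with extra nodes straddling every K (and tungsten L)
#' absorption edge, an elemental K-shell relaxation registry (edge energies,
#' fluorescence yields, K-alpha and KLL Auger energies), and a registry of
#' material compositions (ICRU-44-like mixtures with mass fractions and bulk
#' densities).  Tables were generated once from standard public tabulations
#' (Cromer-Liberman photoelectric cross sections, Klein-Nishina incoherent
#' scattering with form-factor corrections, IT92 elastic form factors) and
#' are stored as plain CSV/JSON under `inst/extdata`.
#'
#' @name materials-data
#' @keywords internal
NULL

kv_tables <- function() {
  if (is.null(.kv$coeff)) {
    path <- system.file("extdata", "photon_coefficients.csv",
                        package = "kvdosim", mustWork = TRUE)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    .kv$coeff <- split(tab, tab$element)
    rpath <- system.file("extdata", "element_relaxation.csv",
                         package = "kvdosim", mustWork = TRUE)
    rel <- read.csv(rpath, stringsAsFactors = FALSE)
    rownames(rel) <- rel$element
    .kv$relax <- rel
    mpath <- system.file("extdata", "materials.json",
                         package = "kvdosim", mustWork = TRUE)
    .kv$materials <- jsonlite::fromJSON(mpath)
    epath <- system.file("extdata", "electron_csda_water.csv",
                         package = "kvdosim", mustWork = TRUE)
    .kv$csda <- read.csv(epath)
  }
  invisible(.kv)
}

#' Define a material from elemental mass fractions
#'
#' @param name material name.
#' @param density bulk density in g/cm^3.
#' @param fractions named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-6).
#' @return an object of class `kv_material`.
#' @examples
#' m <- kv_material("water", 1.0, c(H = 0.111898, O = 0.888102))
#' @export
kv_material <- function(name, density, fractions) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a positive scalar")
  fractions <- unlist(fractions)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be named by element symbol")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (any(fractions < 0)) stop("mass fractions must be non-negative")
  structure(list(name = name, density = density, fractions = fractions),
            class = "kv_material")
}

#' Look up a material from the embedded registry
#'
#' @param name registry name, one of [list_materials()].
#' @return a `kv_material`.
#' @examples
#' get_material("cortical_bone")
#' @export
get_material <- function(name) {
  reg <- kv_tables()$materials
  if (!name %in% names(reg)) {
    stop("unknown material '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  m <- reg[[name]]
  kv_material(name, m$density, unlist(m$fractions))
}

#' @return character vector of registry material names.
#' @rdname get_material
#' @export
list_materials <- function() names(kv_tables()$materials)

#' @export
print.kv_material <- function(x, ...) {
  cat("<kv_material>", x$name, " rho =", x$density, "g/cm^3\n")
  fr <- sort(x$fractions, decreasing = TRUE)
  cat(" ", paste0(names(fr), " ", signif(fr, 3), collapse = ", "), "\n")
  invisible(x)
}

as_kv_material <- function(x) {
  if (inherits(x, "kv_material")) return(x)
  if (is.character(x) && length(x) == 1L) return(get_material(x))
  stop("expected a kv_material or a registry material name")
}

#' Elemental K-shell relaxation data
#'
#' @param element element symbol.
#' @return list with `Z`, `atomic_weight`, `K_edge_keV`,
#'   `K_fluorescence_yield`, `K_alpha_keV`, `KLL_auger_keV` and
#'   `K_shell_fraction` (photoelectric K-shell share just above the edge,
#'   derived from the edge jump ratio).
#' @examples
#' element_data("Ca")$KLL_auger_keV
#' @export
element_data <- function(element) {
  rel <- kv_tables()$relax
  if (!element %in% rownames(rel)) stop("no data for element '", element, "'")
  r <- rel[element, ]
  list(Z = r$Z, atomic_weight = r$atomic_weight, K_edge_keV = r$K_edge_keV,
       K_fluorescence_yield = r$K_fluorescence_yield,
       K_alpha_keV = r$K_alpha_keV, KLL_auger_keV = r$KLL_auger_keV,
       K_shell_fraction = r$K_shell_fraction)
}

.kv_kinds <- c(total = "total", en = "en", photoelectric = "photoelectric",
               compton = "compton", rayleigh = "rayleigh")

#' Interpolate a mass interaction coefficient
#'
#' Log-log linear interpolation of the embedded per-element tables; exact at
#' table nodes.  For a material, the mixture rule
#' \eqn{\sum_i w_i (\mu/\rho)_i} is applied element-wise.
#'
#' @param x element symbol, registry material name, or `kv_material`.
#' @param energy photon energy in keV (vectorized); must lie inside the
#'   tabulated range.
#' @param kind one of `"total"`, `"en"` (energy absorption),
#'   `"photoelectric"`, `"compton"`, `"rayleigh"`.
#' @return mass coefficient(s) in cm^2/g.
#' @examples
#' mass_coefficient("water", 40, "en")
#' mass_coefficient("Cu", c(20, 40, 60), "total")
#' @export
mass_coefficient <- function(x, energy, kind = "total") {
  kind <- match.arg(kind, names(.kv_kinds))
  if (any(!is.finite(energy))) stop("energy must be finite")
  tabs <- kv_tables()$coeff
  if (is.character(x) && length(x) == 1L && x %in% names(tabs)) {
    return(.kv_interp_element(x, energy, kind))
  }
  m <- as_kv_material(x)
  out <- 0
  for (el in names(m$fractions)) {
    w <- m$fractions[[el]]
    if (w > 0) out <- out + w * .kv_interp_element(el, energy, kind)
  }
  out
}

.kv_interp_element <- function(element, energy, kind) {
  tabs <- kv_tables()$coeff
  t <- tabs[[element]]
  if (is.null(t)) stop("no coefficient table for element '", element, "'")
  if (any(energy < min(t$energy_keV) | energy > max(t$energy_keV))) {
    stop("energy outside tabulated range [", min(t$energy_keV), ", ",
         max(t$energy_keV), "] keV for ", element)
  }
  v <- t[[kind]]
  # guard zeros (photoelectric for H is exactly 0 at high energy)
  pos <- v > 0
  if (!all(pos)) {
    out <- approx(t$energy_keV, v, xout = energy, rule = 2)$y
    return(pmax(out, 0))
  }
  exp(approx(log(t$energy_keV), log(v), xout = log(energy), rule = 1)$y)
}

#' Linear attenuation coefficient
#'
#' @inheritParams mass_coefficient
#' @return linear coefficient(s) in 1/cm (mass coefficient times density).
#' @examples
#' linear_attenuation("copper", 40)
#' @export
linear_attenuation <- function(x, energy, kind = "total") {
  m <- as_kv_material(x)
  mass_coefficient(m, energy, kind) * m$density
}

# Z/A of a material (needed for electron stopping-power scaling)
kv_zoa <- function(material) {
  m <- as_kv_material(material)
  rel <- kv_tables()$relax
  s <- 0
  for (el in names(m$fractions)) {
    if (!el %in% rownames(rel)) stop("no Z/A data for element '", el, "'")
    s <- s + m$fractions[[el]] * rel[el, "Z"] / rel[el, "atomic_weight"]
  }
  s
}

# CSDA range (g/cm^2) of an electron of `energy` keV, water-based with a
# Z/A stopping-power scaling for other media
kv_csda_range <- function(energy, material = "water") {
  cs <- kv_tables()$csda
  energy <- pmax(energy, min(cs$energy_keV))
  if (any(energy > max(cs$energy_keV))) stop("electron energy above CSDA table")
  r <- exp(approx(log(cs$energy_keV), log(cs$csda_range_g_cm2),
                  xout = log(energy), rule = 1)$y)
  zoa_w <- 0.111898 * 1 / 1.008 + 0.888102 * 8 / 15.999
  r * zoa_w / kv_zoa(material)
}
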