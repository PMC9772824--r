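#' Slab phantom
#'
#' Ordered stack of material slices along the beam axis (z).  Slice `i`
#' occupies `[slice_mm*(i-1), slice_mm*i)` in depth (half-open).
#'
#' @param materials character vector: material name of every slice, or a
#'   short specification via `segments` (see
#'   [heterogeneous_leg_phantom()]).
#' @param slice_mm slice thickness in mm (default 0.1).
#' @param lateral_mm lateral extent `c(x, y)` in mm.
#' @param segments optional named list of slice-index vectors identifying
#'   tissue segments.
#' @return a `kv_slab_phantom`.
#' @examples
#' homogeneous_phantom("cortical_bone")
#' @export
slab_phantom <- function(materials, slice_mm = 0.1, lateral_mm = c(30, 10),
                         segments = NULL) {
  stopifnot(is.character(materials), length(materials) >= 1)
  if (slice_mm <= 0) stop("slice thickness must be positive")
  reg <- list_materials()
  bad <- setdiff(unique(materials), reg)
  if (length(bad)) stop("unknown material(s): ", paste(bad, collapse = ", "))
  structure(list(slices = materials, slice_mm = slice_mm,
                 lateral_mm = lateral_mm, segments = segments),
            class = "kv_slab_phantom")
}

#' @param material single material name.
#' @param n_slices number of slices (default 70, i.e. 7 mm at 0.1 mm).
#' @rdname slab_phantom
#' @export
homogeneous_phantom <- function(material, n_slices = 70, slice_mm = 0.1,
                                lateral_mm = c(30, 10)) {
  slab_phantom(rep(material, n_slices), slice_mm, lateral_mm,
               segments = setNames(list(seq_len(n_slices)), material))
}

#' Heterogeneous mouse-leg slab phantom
#'
#' The 70-slice, 7 mm stack representative of a mouse leg at the tibial
#' head: 23 slices of soft tissue, 3 of cortical bone, 19 of trabecular
#' bone, 3 of cortical bone and 22 of soft tissue (0.1 mm slices; thickness
#' 2.30 / 0.30 / 1.90 / 0.30 / 2.20 mm).
#'
#' @return a `kv_slab_phantom` with named segments `soft1`, `cortical1`,
#'   `trabecular`, `cortical2`, `soft2` and the combined `bone` segment.
#' @examples
#' ph <- heterogeneous_leg_phantom()
#' table(ph$slices)
#' @export
heterogeneous_leg_phantom <- function() {
  counts <- c(soft1 = 23, cortical1 = 3, trabecular = 19, cortical2 = 3,
              soft2 = 22)
  mats <- rep(c("soft_tissue", "cortical_bone", "trabecular_bone",
                "cortical_bone", "soft_tissue"), counts)
  ends <- cumsum(counts)
  starts <- c(1, ends[-length(ends)] + 1)
  seg <- mapply(seq, starts, ends, SIMPLIFY = FALSE)
  names(seg) <- names(counts)
  seg$bone <- sort(unlist(seg[c("cortical1", "trabecular", "cortical2")],
                          use.names = FALSE))
  slab_phantom(mats, segments = seg)
}

#' @export
print.kv_slab_phantom <- function(x, ...) {
  r <- rle(x$slices)
  cat("<kv_slab_phantom> ", length(x$slices), " x ", x$slice_mm, " mm (",
      length(x$slices) * x$slice_mm, " mm total)\n", sep = "")
  cat(" ", paste0(r$values, ":", r$lengths, collapse = " | "), "\n")
  invisible(x)
}

#' Voxel phantom
#'
#' Rectilinear grid of material indices; the beam travels along the third
#' array dimension (z).
#'
#' @param grid 3-d integer array of material indices (1-based into
#'   `materials`).
#' @param voxel_mm voxel edge length in mm (default 0.09).
#' @param materials character vector of material names indexed by `grid`.
#' @return a `kv_voxel_phantom`.
#' @export
voxel_phantom <- function(grid, voxel_mm = 0.09, materials) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (voxel_mm <= 0) stop("voxel size must be positive")
  idx <- unique(as.integer(grid))
  if (any(idx < 1L) || any(idx > length(materials)))
    stop("grid contains indices outside the material list")
  bad <- setdiff(materials, list_materials())
  if (length(bad)) stop("unknown material(s): ", paste(bad, collapse = ", "))
  structure(list(grid = grid, voxel_mm = voxel_mm, materials = materials),
            class = "kv_voxel_phantom")
}

#' @export
print.kv_voxel_phantom <- function(x, ...) {
  d <- dim(x$grid)
  cat("<kv_voxel_phantom> ", paste(d, collapse = " x "), " voxels of ",
      x$voxel_mm, " mm\n", sep = "")
  tb <- table(factor(x$materials[x$grid], levels = x$materials))
  print(tb)
  invisible(x)
}

#' Synthetic voxelized mouse-leg phantom
#'
#' Concentric-cylinder stand-in for a segmented microCT mouse leg: a
#' soft-tissue cylinder containing a cortical-bone shell around a marrow
#' core, embedded in air, with the cylinder axis perpendicular to the beam
#' (beam along z, axis along x).
#'
#' @param outer_diameter_mm soft-tissue cylinder diameter (default 5).
#' @param cortical_thickness_mm cortical shell thickness (default 0.3).
#' @param marrow_diameter_mm marrow core diameter (default 0.9; 0 gives a
#'   two-material phantom with a solid bone core).
#' @param voxel_mm voxel size (default 0.09, i.e. 90 um).
#' @param length_mm cylinder length along its axis (default 2.7).
#' @return a `kv_voxel_phantom` with materials
#'   `air`/`soft_tissue`/`cortical_bone`/`bone_marrow`.
#' @examples
#' leg <- build_leg_voxel_phantom()
#' dim(leg$grid)
#' @export
build_leg_voxel_phantom <- function(outer_diameter_mm = 5,
                                    cortical_thickness_mm = 0.3,
                                    marrow_diameter_mm = 0.9,
                                    voxel_mm = 0.09, length_mm = 2.7) {
  r_out <- outer_diameter_mm / 2
  r_marrow <- marrow_diameter_mm / 2
  r_bone <- r_marrow + cortical_thickness_mm
  if (r_marrow < 0 || cortical_thickness_mm <= 0)
    stop("non-physical diameters")
  if (r_bone > r_out)
    stop("bone shell does not fit inside the soft-tissue cylinder")
  mats <- c("air", "soft_tissue", "cortical_bone", "bone_marrow")
  nx <- max(1L, ceiling(length_mm / voxel_mm))
  nyz <- ceiling(outer_diameter_mm / voxel_mm)
  cyz <- (nyz * voxel_mm) / 2
  centers <- (seq_len(nyz) - 0.5) * voxel_mm - cyz
  rad <- sqrt(outer(centers^2, centers^2, "+"))  # radius in the y-z plane
  plane <- matrix(1L, nyz, nyz)
  plane[rad <= r_out] <- 2L
  plane[rad <= r_bone] <- 3L
  if (r_marrow > 0) plane[rad <= r_marrow] <- 4L
  grid <- array(rep(plane, each = nx), dim = c(nx, nyz, nyz))
  voxel_phantom(grid, voxel_mm, mats)
}
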