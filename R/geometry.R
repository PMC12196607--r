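#' Grid geometry of a volume
#'
#' Describes the sampling lattice shared by all volumes of one patient
#' series: array shape, voxel spacing in mm, and the physical (mm)
#' coordinate of the center of voxel (0,0,0). Axes are assumed aligned with
#' the physical axes (the pipeline harmonizes grids but never estimates
#' rotations; inter-timepoint registration is assumed already done
#' upstream).
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param spacing_mm numeric vector of length 3, voxel edge lengths in mm.
#' @param origin_mm numeric vector of length 3, physical coordinate (mm) of
#'   the center of the first voxel. Defaults to the grid centered on 0.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, spacing_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(shape) == 3L, length(spacing_mm) == 3L)
  if (any(shape < 1L)) stop("grid shape must be positive", call. = FALSE)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("voxel spacing must be strictly positive", call. = FALSE)
  if (is.null(origin_mm)) origin_mm <- -(shape - 1) * spacing_mm / 2
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("%s@%s", paste(x$shape, collapse = "x"),
          paste(format(x$spacing_mm, trim = TRUE), collapse = "x"))
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("volumes are not on the same grid (",
         format(a), " vs ", format(b), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Affine matrix of a grid (voxel index, 0-based, to mm)
#' @param geom a `grid_geometry`.
#' @return 4x4 affine matrix mapping 0-based voxel indices to mm.
#' @export
grid_affine <- function(geom) {
  aff <- diag(c(geom$spacing_mm, 1))
  aff[1:3, 4] <- geom$origin_mm
  aff
}

geometry_from_affine <- function(shape, aff) {
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid_geometry(shape, sp, aff[1:3, 4])
}

#' Physical coordinates of voxel centers
#'
#' @param geom a `grid_geometry`.
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(geom, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, geom$spacing_mm, `*`), 2, geom$origin_mm, `+`)
}

mm_to_voxel <- function(geom, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, geom$origin_mm, `-`), 2, geom$spacing_mm, `/`)
}

#' Volume of one voxel in microliters
#'
#' One microliter equals one cubic millimeter, so this is the product of
#' the voxel spacings. `interpolated_voxel_volume_ul()` gives the voxel
#' volume implied by a field of view divided into a reconstruction matrix,
#' e.g. a 280 x 280 x 180 mm spectroscopic FOV reconstructed on a
#' 64 x 64 x 32 grid yields 107.7 uL, quoted as 108 uL at whole-uL
#' precision.
#'
#' @param geom a `grid_geometry`.
#' @return voxel volume in microliters.
#' @export
voxel_volume_ul <- function(geom) prod(geom$spacing_mm)

#' @rdname voxel_volume_ul
#' @param fov_mm field of view per axis, mm (length 3).
#' @param matrix_size reconstruction matrix per axis (length 3).
#' @export
interpolated_voxel_volume_ul <- function(fov_mm, matrix_size) {
  stopifnot(length(fov_mm) == 3L, length(matrix_size) == 3L,
            all(fov_mm > 0), all(matrix_size >= 1))
  prod(fov_mm / matrix_size)
}

# 0-based index grid of all voxels, n x 3 (column-major order)
all_voxel_indices <- function(shape) {
  as.matrix(expand.grid(i = 0:(shape[1] - 1L),
                        j = 0:(shape[2] - 1L),
                        k = 0:(shape[3] - 1L)))
}
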