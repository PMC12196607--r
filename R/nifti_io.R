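#' Write a volume or mask to NIfTI
#'
#' Metabolite maps are written as two files: `<path>` with the values
#' (uncovered voxels hold 0) and `<stem>_coverage.nii[.gz]` with the
#' coverage lattice. Masks are written as a single 0/1 volume. The grid
#' geometry goes into the sform/qform affine (0-based voxel index to mm).
#'
#' @param x a [metabolite_map()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, the character vector of paths written.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "metabolite_map")) {
    vals <- x$values
    vals[!x$coverage] <- 0
    paths <- c(path, coverage_path(path))
    write_nifti_array(vals, x$geometry, path)
    write_nifti_array(x$coverage * 1, x$geometry, paths[2])
  } else if (inherits(x, "binary_mask")) {
    paths <- path
    write_nifti_array(x$values * 1, x$geometry, path)
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  invisible(paths)
}

coverage_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "_coverage.nii\\1", path)
}

write_nifti_array <- function(arr, geom, path) {
  im <- RNifti::asNifti(arr + 0)  # force numeric storage
  RNifti::pixdim(im) <- geom$spacing_mm
  aff <- grid_affine(geom)
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(path, " is not a 3D volume (dim ", paste(d, collapse = "x"), ")",
         call. = FALSE)
  aff <- RNifti::xform(im)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(path, ": header has no usable voxel spacing", call. = FALSE)
  list(values = arr, geometry = geometry_from_affine(d, aff))
}

#' Read a volume or mask from NIfTI
#'
#' `expected_kind = "mask"` coerces to 0/1 and rejects any file whose
#' values are not all within tolerance of 0 or 1. For metabolite kinds a
#' companion `<stem>_coverage` file is read when present; otherwise every
#' finite voxel counts as covered.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param expected_kind one of `"CHO"`, `"NAA"`, `"CHO_NAA_RATIO"` (returns
#'   a [metabolite_map()]) or `"mask"` (returns a [binary_mask()]).
#' @param label mask label when `expected_kind = "mask"`.
#' @return A [metabolite_map()] or [binary_mask()].
#' @export
read_volume <- function(path, expected_kind, label = "GROUND_TRUTH") {
  expected_kind <- match.arg(expected_kind, c(METABOLITE_KINDS, "mask"))
  x <- read_nifti_array(path)
  if (expected_kind == "mask") {
    v <- x$values
    if (any(!is.finite(v)) || any(abs(v) > 1e-6 & abs(v - 1) > 1e-6))
      stop(path, " read as mask but contains non-binary values",
           call. = FALSE)
    return(binary_mask(v > 0.5, x$geometry, label))
  }
  covp <- coverage_path(path)
  if (file.exists(covp)) {
    cov <- read_nifti_array(covp)
    coverage <- cov$values > 0.5
  } else {
    coverage <- is.finite(x$values)
  }
  vals <- x$values
  vals[!coverage] <- 0
  metabolite_map(vals, coverage, x$geometry, expected_kind)
}

#' Resample a volume onto a target grid
#'
#' Harmonizes grids after upstream registration; never estimates a
#' transform. Masks and coverage are resampled nearest-neighbour (so they
#' stay binary); metabolite values are interpolated trilinearly, restricted
#' to coverage: a target voxel is covered only if all eight contributing
#' source corners are inside the source grid and covered, so no value is
#' ever fabricated from missing data.
#'
#' @param x a [metabolite_map()] or [binary_mask()].
#' @param target a [grid_geometry()].
#' @return The same kind of object on `target`.
#' @export
resample_to_grid <- function(x, target) {
  stopifnot(inherits(target, "grid_geometry"))
  src_geom <- x$geometry
  if (same_geometry(src_geom, target)) return(replace_geometry(x, target))
  idx <- all_voxel_indices(target$shape)
  src_idx <- mm_to_voxel(src_geom, voxel_to_mm(target, idx))
  inside_nn <- rowSums(src_idx > -0.5) == 3 &
    src_idx[, 1] < src_geom$shape[1] - 0.5 &
    src_idx[, 2] < src_geom$shape[2] - 0.5 &
    src_idx[, 3] < src_geom$shape[3] - 0.5
  if (!any(inside_nn))
    stop("no spatial overlap between source and target grids",
         call. = FALSE)
  if (inherits(x, "binary_mask")) {
    out <- array(FALSE, dim = target$shape)
    nn <- round(src_idx[inside_nn, , drop = FALSE]) + 1L
    out[inside_nn] <- x$values[cbind(nn[, 1], nn[, 2], nn[, 3])]
    return(binary_mask(out, target, x$label))
  }
  tl <- trilinear_with_coverage(x$values, x$coverage, src_idx)
  vals <- array(0, dim = target$shape)
  vals[tl$covered] <- tl$values[tl$covered]
  metabolite_map(vals, array(tl$covered, dim = target$shape), target,
                 x$metabolite)
}

replace_geometry <- function(x, target) {
  x$geometry <- target
  x
}

# Trilinear interpolation at continuous 0-based source indices, with
# coverage propagation: covered only where all 8 corners exist & covered.
trilinear_with_coverage <- function(values, coverage, sidx) {
  sh <- dim(values)
  f <- floor(sidx)
  w <- sidx - f
  vals <- numeric(nrow(sidx))
  cov <- rep(TRUE, nrow(sidx))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ci <- f[, 1] + dx; cj <- f[, 2] + dy; ck <- f[, 3] + dz
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
      (if (dy == 1) w[, 2] else 1 - w[, 2]) *
      (if (dz == 1) w[, 3] else 1 - w[, 3])
    inside <- ci >= 0 & cj >= 0 & ck >= 0 &
      ci <= sh[1] - 1 & cj <= sh[2] - 1 & ck <= sh[3] - 1
    contributes <- wt > 1e-12
    corner_cov <- rep(FALSE, length(ci))
    if (any(inside))
      corner_cov[inside] <- coverage[cbind(ci[inside] + 1, cj[inside] + 1,
                                           ck[inside] + 1)]
    cov <- cov & (!contributes | corner_cov)
    use <- inside & contributes
    if (any(use)) {
      vals[use] <- vals[use] +
        wt[use] * values[cbind(ci[use] + 1, cj[use] + 1, ck[use] + 1)]
    }
  }
  list(values = vals, covered = cov)
}
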