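#' Dice similarity coefficient between two masks
#'
#' `2|A∩B| / (|A|+|B|)`, in `[0, 1]`; 0 means no overlap, 1 perfect
#' agreement. Degenerate cases: both masks empty is defined as perfect
#' agreement (1) with a warning flag so cohort batteries over responders
#' whose lesion vanished do not crash; exactly one empty mask gives 0.
#'
#' @param a,b [binary_mask()]s on a shared grid.
#' @return Dice coefficient; attribute `"both_empty"` flags the degenerate
#'   case.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_geometry_mismatch(a$geometry, b$geometry)
  na <- sum(a$values); nb <- sum(b$values)
  if (na == 0L && nb == 0L) {
    warning("both masks empty; Dice defined as 1", call. = FALSE)
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(a$values & b$values) / (na + nb)
}

#' Boundary points of a mask in physical coordinates
#'
#' A mask voxel is a boundary voxel when at least one of its six
#' face-adjacent neighbours is outside the mask or outside the grid.
#' Returns the physical (mm) coordinates of the boundary voxel centers.
#'
#' @param mask a nonempty [binary_mask()].
#' @return n x 3 matrix of mm coordinates.
#' @export
boundary_points <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("mask is empty; no boundary", call. = FALSE)
  b <- boundary_voxels(mask$values)
  idx <- which(b)
  ai <- arrayInd(idx, dim(mask$values)) - 1L
  voxel_to_mm(mask$geometry, ai)
}

# logical array of boundary voxels (6-connectivity complement test)
boundary_voxels <- function(arr) {
  d <- dim(arr)
  interior <- array(TRUE, dim = d)
  shift_covered <- function(axis, dir) {
    out <- array(FALSE, dim = d)
    n <- d[axis]
    if (n == 1L) return(out)
    src <- 1:(n - 1L)
    if (axis == 1L) {
      if (dir > 0) out[src + 1L, , ] <- arr[src, , ]
      else out[src, , ] <- arr[src + 1L, , ]
    } else if (axis == 2L) {
      if (dir > 0) out[, src + 1L, ] <- arr[, src, ]
      else out[, src, ] <- arr[, src + 1L, ]
    } else {
      if (dir > 0) out[, , src + 1L] <- arr[, , src]
      else out[, , src] <- arr[, , src + 1L]
    }
    out
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_covered(axis, dir)
  arr & !interior
}

#' Hausdorff distance between two masks, in mm
#'
#' The maximum over one mask's boundary of the Euclidean distance to the
#' nearest boundary point of the other, symmetrized by taking the larger
#' of the two directed values. Boundaries use the 6-connectivity surface
#' voxel definition of [boundary_points()]; distances are between voxel
#' centers in mm. The full (100th percentile) Hausdorff is the default; a
#' percentile (e.g. 95) is available for robustness studies.
#'
#' @param a,b nonempty [binary_mask()]s on a shared grid.
#' @param percentile percentile of directed boundary distances (100 =
#'   classical maximum).
#' @return Hausdorff distance in mm.
#' @export
hausdorff_mm <- function(a, b, percentile = 100) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_geometry_mismatch(a$geometry, b$geometry)
  if (!any(a$values) || !any(b$values)) {
    cond <- structure(
      class = c("smritrack_empty_mask", "error", "condition"),
      list(message = "Hausdorff distance undefined for an empty mask",
           call = sys.call(-1)))
    stop(cond)
  }
  pa <- boundary_points(a)
  pb <- boundary_points(b)
  d_ab <- directed_min_dists(pa, pb)
  d_ba <- directed_min_dists(pb, pa)
  if (percentile >= 100) max(max(d_ab), max(d_ba))
  else max(stats::quantile(d_ab, percentile / 100, names = FALSE),
           stats::quantile(d_ba, percentile / 100, names = FALSE))
}

# for each row of p, min Euclidean distance to rows of q (chunked)
directed_min_dists <- function(p, q, chunk = 512L) {
  qq <- rowSums(q^2)
  out <- numeric(nrow(p))
  for (s in seq(1L, nrow(p), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(p))
    pc <- p[s:e, , drop = FALSE]
    d2 <- outer(rowSums(pc^2), qq, `+`) - 2 * pc %*% t(q)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Pre-RT vs post-RT overlap battery for one series
#'
#' For one mask family, compares the single pre-RT timepoint's mask with
#' each post-RT timepoint's mask: one record per post-RT timepoint with
#' Dice, Hausdorff (mm), voxel counts and flags. Pairs where the Hausdorff
#' distance is undefined (an empty mask) are flagged, never silently
#' dropped.
#'
#' @param series a [patient_series()] whose timepoints carry masks of the
#'   family.
#' @param mask_family `"CHO_NAA_2X"` or `"FLAIR"`.
#' @return data.frame with one row per post-RT timepoint: `patient`,
#'   `pre_months`, `post_months`, `family`, `dsc`, `hd_mm`,
#'   `n_ref_voxels`, `n_cmp_voxels`, `flags`.
#' @export
overlap_battery <- function(series, mask_family = c("CHO_NAA_2X", "FLAIR")) {
  mask_family <- match.arg(mask_family)
  stopifnot(inherits(series, "patient_series"))
  pre <- series$timepoints[[series$pre_index]]
  ref <- pre$masks[[mask_family]]
  if (is.null(ref))
    stop("pre-RT timepoint lacks a ", mask_family, " mask", call. = FALSE)
  posts <- post_indices(series)
  rows <- lapply(posts, function(i) {
    tp <- series$timepoints[[i]]
    cmp <- tp$masks[[mask_family]]
    if (is.null(cmp)) {
      return(data.frame(patient = series$patient_id,
                        pre_months = pre$months_from_rt,
                        post_months = tp$months_from_rt,
                        family = mask_family, dsc = NA_real_,
                        hd_mm = NA_real_, n_ref_voxels = sum(ref$values),
                        n_cmp_voxels = NA_integer_,
                        flags = "missing_mask"))
    }
    flags <- character()
    dsc <- withCallingHandlers(
      dice(ref, cmp),
      warning = function(w) {
        flags <<- c(flags, "both_empty"); invokeRestart("muffleWarning")
      })
    hd <- tryCatch(hausdorff_mm(ref, cmp),
                   smritrack_empty_mask = function(e) {
                     flags <<- c(flags, "hd_undefined"); NA_real_
                   })
    data.frame(patient = series$patient_id,
               pre_months = pre$months_from_rt,
               post_months = tp$months_from_rt,
               family = mask_family, dsc = as.numeric(dsc), hd_mm = hd,
               n_ref_voxels = sum(ref$values),
               n_cmp_voxels = sum(cmp$values),
               flags = paste(flags, collapse = ";"))
  })
  do.call(rbind, rows)
}
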