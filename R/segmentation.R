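#' Voxelwise Cho/NAA ratio map
#'
#' Computed on the intersection of the two coverages. Voxels whose NAA
#' falls below a small positive floor are removed from the output coverage
#' rather than clipped, so no fabricated extreme ratios enter the
#' segmentation. The floor defaults to 1e-6 times the median NAA over
#' coverage.
#'
#' @param cho,naa [metabolite_map()]s on a shared grid.
#' @param naa_floor positive floor below which NAA voxels are excluded;
#'   `NULL` for the median-scaled default.
#' @return A `CHO_NAA_RATIO` [metabolite_map()].
#' @export
ratio_map <- function(cho, naa, naa_floor = NULL) {
  stopifnot(inherits(cho, "metabolite_map"), cho$metabolite == "CHO",
            inherits(naa, "metabolite_map"), naa$metabolite == "NAA")
  stop_if_geometry_mismatch(cho$geometry, naa$geometry)
  cov <- cho$coverage & naa$coverage
  if (is.null(naa_floor)) {
    med <- stats::median(naa$values[naa$coverage])
    naa_floor <- 1e-6 * max(med, .Machine$double.eps)
  }
  cov <- cov & (naa$values >= naa_floor)
  vals <- array(0, dim = dim(cho$values))
  vals[cov] <- cho$values[cov] / naa$values[cov]
  metabolite_map(vals, cov, cho$geometry, "CHO_NAA_RATIO")
}

#' Contralateral NAWM reference for the 2X threshold
#'
#' The biomarker threshold is defined relative to the average Cho/NAA in
#' normal-appearing white matter on the side of the brain opposite the
#' tumor. The reference is the arithmetic mean of the ratio over the NAWM
#' mask intersected with ratio coverage (`stat = "median"` is available
#' for sensitivity checks but is never the default).
#'
#' @param ratio a `CHO_NAA_RATIO` [metabolite_map()].
#' @param nawm a NAWM [binary_mask()].
#' @param min_voxels minimum voxels required in the reference region.
#' @param stat `"mean"` (default) or `"median"`.
#' @param source provenance tag, `"MANUAL_MASK"` or `"MIRRORED"`.
#' @return An object of class `nawm_reference` with fields `mean_ratio`,
#'   `n_voxels`, `source`.
#' @export
nawm_reference <- function(ratio, nawm, min_voxels = 50,
                           stat = c("mean", "median"),
                           source = c("MANUAL_MASK", "MIRRORED")) {
  stat <- match.arg(stat)
  source <- match.arg(source)
  stopifnot(inherits(ratio, "metabolite_map"),
            ratio$metabolite == "CHO_NAA_RATIO",
            inherits(nawm, "binary_mask"))
  stop_if_geometry_mismatch(ratio$geometry, nawm$geometry)
  sel <- nawm$values & ratio$coverage
  n <- sum(sel)
  if (n < min_voxels)
    stop("NAWM reference region has ", n, " voxels inside ratio coverage; ",
         min_voxels, " required", call. = FALSE)
  m <- if (stat == "mean") mean(ratio$values[sel])
       else stats::median(ratio$values[sel])
  if (!is.finite(m) || m <= 0)
    stop("NAWM reference ratio is not finite and positive", call. = FALSE)
  structure(list(mean_ratio = m, n_voxels = n, source = source, stat = stat),
            class = "nawm_reference")
}

#' @export
print.nawm_reference <- function(x, ...) {
  cat(sprintf("nawm_reference: %s ratio %.4f over %d voxels (%s)\n",
              x$stat, x$mean_ratio, x$n_voxels, x$source))
  invisible(x)
}

#' Mirror a lesion mask across the mid-sagittal plane
#'
#' Fallback NAWM region when no manual reference mask is supplied: the
#' lesion (or FLAIR) mask reflected across the mid-sagittal grid plane
#' (first axis), intersected with the brain and with the lesion's
#' complement. A midline lesion overlapping its own mirror loses the
#' overlapping voxels; an entirely self-overlapping mirror is an error and
#' the caller must supply a manual mask.
#'
#' @param lesion lesion or FLAIR [binary_mask()].
#' @param brain brain [binary_mask()].
#' @return A NAWM [binary_mask()].
#' @export
mirror_nawm <- function(lesion, brain) {
  stopifnot(inherits(lesion, "binary_mask"), inherits(brain, "binary_mask"))
  stop_if_geometry_mismatch(lesion$geometry, brain$geometry)
  if (!any(brain$values)) stop("brain mask is empty", call. = FALSE)
  if (!any(lesion$values)) stop("lesion mask is empty", call. = FALSE)
  mirrored <- lesion$values[dim(lesion$values)[1]:1, , , drop = FALSE]
  out <- mirrored & brain$values & !lesion$values
  if (!any(out))
    stop("mirrored NAWM region is empty (midline lesion?); ",
         "supply a manual NAWM mask", call. = FALSE)
  binary_mask(out, lesion$geometry, "NAWM")
}

#' Segment the Cho/NAA >= 2X biomarker region
#'
#' Voxels whose ratio is at least `factor` times the NAWM reference mean,
#' inside ratio coverage. The comparison is inclusive (>=), matching the
#' biomarker's definition. Connected components (26-connectivity) smaller
#' than `min_component_cc` are removed — a size filter standing in for the
#' expert review and manual contour editing applied to clinical
#' segmentations.
#'
#' @param ratio a `CHO_NAA_RATIO` [metabolite_map()].
#' @param ref a [nawm_reference()].
#' @param factor threshold multiple of the reference (default 2).
#' @param min_component_cc minimum connected-component volume retained, cc.
#' @return A `CHO_NAA_2X` [binary_mask()] (possibly empty).
#' @export
threshold_mask <- function(ratio, ref, factor = 2.0, min_component_cc = 0.1) {
  stopifnot(inherits(ratio, "metabolite_map"),
            ratio$metabolite == "CHO_NAA_RATIO",
            inherits(ref, "nawm_reference"),
            is.finite(factor), factor > 0, min_component_cc >= 0)
  sel <- ratio$coverage & (ratio$values >= factor * ref$mean_ratio)
  mask <- binary_mask(array(sel, dim = dim(ratio$values)), ratio$geometry,
                      "CHO_NAA_2X")
  if (min_component_cc > 0 && any(mask$values))
    mask <- filter_small_components(mask, min_component_cc)
  mask
}

#' Remove small connected components from a mask
#'
#' @param mask a [binary_mask()].
#' @param min_cc minimum component volume retained, cc.
#' @param connectivity 26 (default) or 6.
#' @return The filtered [binary_mask()].
#' @export
filter_small_components <- function(mask, min_cc, connectivity = 26) {
  labels <- label_components(mask$values, connectivity)
  if (max(labels) == 0L) return(mask)
  vox_cc <- voxel_volume_ul(mask$geometry) / 1000
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes * vox_cc >= min_cc)
  out <- array(labels %in% keep & labels > 0L, dim = dim(mask$values))
  binary_mask(out, mask$geometry, mask$label)
}

# Connected-component labeling of a 3D logical array via the voxel
# adjacency graph (igraph handles the union-find).
label_components <- function(arr, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  idx <- which(arr)
  labels <- array(0L, dim = dim(arr))
  if (length(idx) == 0L) return(labels)
  d <- dim(arr)
  ai <- arrayInd(idx, d)
  pos <- rep(NA_integer_, prod(d))
  pos[idx] <- seq_along(idx)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  if (connectivity == 6)
    offsets <- offsets[rowSums(abs(offsets)) == 1, , drop = FALSE]
  # each unordered pair appears once: keep lexicographically positive offsets
  keep <- offsets[, 3] > 0 |
    (offsets[, 3] == 0 & (offsets[, 2] > 0 |
                            (offsets[, 2] == 0 & offsets[, 1] > 0)))
  offsets <- offsets[keep, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    ni <- ai[, 1] + offsets[r, 1]
    nj <- ai[, 2] + offsets[r, 2]
    nk <- ai[, 3] + offsets[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    if (!any(ok)) next
    lin <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
    nb <- pos[lin]
    src <- which(ok)[!is.na(nb)]
    if (length(src))
      edges[[length(edges) + 1L]] <- cbind(src, nb[!is.na(nb)])
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(idx)
  }
  labels[idx] <- as.integer(comp)
  labels
}

#' Segment one timepoint end to end
#'
#' Ratio map, NAWM reference (manual mask if present on the timepoint,
#' otherwise mirrored ground-truth/FLAIR lesion), threshold at
#' `factor` times the reference. The resulting `CHO_NAA_2X` mask is
#' attached to the returned timepoint.
#'
#' @param tp a [timepoint()].
#' @param factor threshold multiple (default 2).
#' @param min_component_cc size filter, cc.
#' @param exclusion optional [binary_mask()] of voxels to exclude (e.g.
#'   post-surgical enhancement supplied by the user).
#' @return The timepoint with `masks$CHO_NAA_2X` set and attribute-free
#'   reference recorded in `masks$CHO_NAA_2X$ref` alongside.
#' @export
segment_timepoint <- function(tp, factor = 2.0, min_component_cc = 0.1,
                              exclusion = NULL) {
  rmap <- ratio_map(tp$cho, tp$naa)
  if (!is.null(tp$masks$NAWM)) {
    ref <- nawm_reference(rmap, tp$masks$NAWM, source = "MANUAL_MASK")
  } else {
    lesion <- tp$masks$GROUND_TRUTH %||% tp$masks$FLAIR
    if (is.null(lesion) || is.null(tp$masks$BRAIN))
      stop("no NAWM mask and no lesion+brain masks to mirror", call. = FALSE)
    ref <- nawm_reference(rmap, mirror_nawm(lesion, tp$masks$BRAIN),
                          source = "MIRRORED")
  }
  mask <- threshold_mask(rmap, ref, factor, min_component_cc)
  if (!is.null(exclusion)) {
    stop_if_geometry_mismatch(mask$geometry, exclusion$geometry)
    mask <- binary_mask(mask$values & !exclusion$values, mask$geometry,
                        "CHO_NAA_2X")
  }
  tp$masks$CHO_NAA_2X <- mask
  tp$ratio <- rmap
  tp$nawm_ref <- ref
  tp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
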