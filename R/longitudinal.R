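#' Coverage-match two metabolite maps
#'
#' Restricts both maps to the intersection of their coverages: voxels
#' lacking data at either timepoint are excluded from both, so later
#' voxelwise comparisons never mix measured with missing data.
#'
#' @param m1,m2 [metabolite_map()]s of the same metabolite on a shared
#'   grid.
#' @return List of the two matched maps.
#' @export
coverage_match <- function(m1, m2) {
  stopifnot(inherits(m1, "metabolite_map"), inherits(m2, "metabolite_map"))
  if (m1$metabolite != m2$metabolite)
    stop("cannot coverage-match different metabolites", call. = FALSE)
  stop_if_geometry_mismatch(m1$geometry, m2$geometry)
  cov <- m1$coverage & m2$coverage
  if (!any(cov))
    stop("coverage intersection is empty; pair unusable", call. = FALSE)
  restrict <- function(m) {
    v <- m$values
    v[!cov] <- 0
    metabolite_map(v, cov, m$geometry, m$metabolite)
  }
  list(restrict(m1), restrict(m2))
}

#' Signed voxel-level metabolite difference map
#'
#' Later minus earlier on the matched coverage; positive values mean an
#' increase in the metabolite (rendered red in the standard display),
#' negative a decrease (blue). Antisymmetric under swapping the pair.
#'
#' @param earlier,later coverage-matched [metabolite_map()]s (run
#'   [coverage_match()] first; mismatched coverages are an error).
#' @param pair optional character vector of length 2 naming the
#'   timepoints.
#' @return An object of class `difference_map` with fields `metabolite`,
#'   `values`, `matched_coverage`, `geometry`, `pair`.
#' @export
difference_map <- function(earlier, later, pair = c("earlier", "later")) {
  stopifnot(inherits(earlier, "metabolite_map"),
            inherits(later, "metabolite_map"))
  if (earlier$metabolite != later$metabolite)
    stop("difference of different metabolites", call. = FALSE)
  stop_if_geometry_mismatch(earlier$geometry, later$geometry)
  if (!identical(earlier$coverage, later$coverage))
    stop("coverages not matched; run coverage_match() first", call. = FALSE)
  vals <- later$values - earlier$values
  vals[!earlier$coverage] <- 0
  structure(list(metabolite = earlier$metabolite, values = vals,
                 matched_coverage = earlier$coverage,
                 geometry = earlier$geometry,
                 pair = pair),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  v <- x$values[x$matched_coverage]
  cat(sprintf(
    "difference_map <%s> %s -> %s: median %+.4f over %d matched voxels\n",
    x$metabolite, x$pair[1], x$pair[2], stats::median(v), length(v)))
  invisible(x)
}

#' Volume and percent-change trajectory of a mask family
#'
#' Per-timepoint volumes in cc and the percent change of each scan
#' relative to the immediately preceding scan,
#' `100 * (V_i - V_{i-1}) / V_{i-1}`. A percent change following a
#' zero-volume scan is undefined and flagged `NA`; timepoints missing the
#' mask yield flagged gaps.
#'
#' @param series a [patient_series()].
#' @param mask_family `"CHO_NAA_2X"` or `"FLAIR"`.
#' @return data.frame with `patient`, `months_from_rt`, `family`,
#'   `volume_cc`, `percent_change`, `flags`.
#' @export
volume_trajectory <- function(series, mask_family = c("CHO_NAA_2X", "FLAIR")) {
  mask_family <- match.arg(mask_family)
  stopifnot(inherits(series, "patient_series"),
            length(series$timepoints) >= 2L)
  vols <- vapply(series$timepoints, function(tp) {
    m <- tp$masks[[mask_family]]
    if (is.null(m)) NA_real_ else volume_cc(m)
  }, numeric(1))
  n <- length(vols)
  pc <- rep(NA_real_, n)
  flags <- character(n)
  flags[is.na(vols)] <- "missing_mask"
  for (i in 2:n) {
    if (is.na(vols[i]) || is.na(vols[i - 1])) next
    if (vols[i - 1] == 0) {
      flags[i] <- paste0(flags[i], if (nzchar(flags[i])) ";",
                         "pct_undefined_zero_previous")
    } else {
      pc[i] <- 100 * (vols[i] - vols[i - 1]) / vols[i - 1]
    }
  }
  data.frame(patient = series$patient_id,
             months_from_rt = series$months,
             family = mask_family, volume_cc = vols,
             percent_change = pc, flags = flags)
}

#' Classify an interval as true progression vs pseudoprogression
#'
#' Summarizes the voxelwise Cho and Cho/NAA changes over a region of
#' interest by their medians and applies the sign rule: concurrent
#' increases of both Cho/NAA and Cho mark true progression (tumor growth
#' with active membrane turnover), while a rising Cho/NAA with a
#' paradoxically falling Cho marks pseudoprogression (treatment effect:
#' NAA falls without tumor-driven Cho production). Anything else —
#' including changes inside the dead bands — is stable or response.
#'
#' @param dm_cho a `CHO` [difference_map()].
#' @param dm_ratio a `CHO_NAA_RATIO` [difference_map()] on the same pair.
#' @param roi [binary_mask()] region of interest (conventionally the union
#'   of the pair's CHO_NAA_2X masks).
#' @param dead_band_cho minimum |median ΔCho| treated as a real change
#'   (same units as Cho; default 5% of a NAWM Cho of 1).
#' @param dead_band_ratio minimum |median Δ(Cho/NAA)| treated as a real
#'   change (ratio units).
#' @return An object of class `progression_call` with fields `label`
#'   (`"TRUE_PROGRESSION"`, `"PSEUDOPROGRESSION"`, or
#'   `"STABLE_OR_RESPONSE"`), `delta_cho_summary`, `delta_ratio_summary`,
#'   `roi_voxels`, `dead_band_cho`, `dead_band_ratio`, `pair`.
#' @export
classify_interval <- function(dm_cho, dm_ratio, roi,
                              dead_band_cho = 0.05,
                              dead_band_ratio = 0.1) {
  stopifnot(inherits(dm_cho, "difference_map"), dm_cho$metabolite == "CHO",
            inherits(dm_ratio, "difference_map"),
            dm_ratio$metabolite == "CHO_NAA_RATIO",
            inherits(roi, "binary_mask"),
            dead_band_cho >= 0, dead_band_ratio >= 0)
  stop_if_geometry_mismatch(dm_cho$geometry, dm_ratio$geometry)
  stop_if_geometry_mismatch(dm_cho$geometry, roi$geometry)
  if (!identical(dm_cho$pair, dm_ratio$pair))
    stop("difference maps are not from the same timepoint pair",
         call. = FALSE)
  sel_cho <- roi$values & dm_cho$matched_coverage
  sel_ratio <- roi$values & dm_ratio$matched_coverage
  if (!any(sel_cho) || !any(sel_ratio))
    stop("ROI does not intersect the matched coverage", call. = FALSE)
  d_cho <- stats::median(dm_cho$values[sel_cho])
  d_ratio <- stats::median(dm_ratio$values[sel_ratio])
  label <- if (d_ratio > dead_band_ratio && d_cho > dead_band_cho) {
    "TRUE_PROGRESSION"
  } else if (d_ratio > dead_band_ratio && d_cho < -dead_band_cho) {
    "PSEUDOPROGRESSION"
  } else {
    "STABLE_OR_RESPONSE"
  }
  structure(list(pair = dm_cho$pair, label = label,
                 delta_cho_summary = d_cho, delta_ratio_summary = d_ratio,
                 roi_voxels = sum(sel_cho & sel_ratio),
                 dead_band_cho = dead_band_cho,
                 dead_band_ratio = dead_band_ratio),
            class = "progression_call")
}

#' @export
print.progression_call <- function(x, ...) {
  cat(sprintf(
    "progression_call %s -> %s: %s (median dCho %+.4f, median dRatio %+.4f, %d ROI voxels)\n",
    x$pair[1], x$pair[2], x$label, x$delta_cho_summary,
    x$delta_ratio_summary, x$roi_voxels))
  invisible(x)
}

#' Difference maps and progression calls along a series
#'
#' For each pair of timepoints — consecutive in scan order by default, or
#' each post-RT scan against the pre-RT baseline — coverage-matches the
#' Cho and ratio maps, forms the signed difference maps, and classifies
#' the interval. Timepoints must have been segmented first
#' ([segment_timepoint()]) so ratio maps and `CHO_NAA_2X` masks exist; the
#' classification ROI is the union of the pair's `CHO_NAA_2X` masks
#' (falling back to the pair's ground-truth masks when both 2X masks are
#' empty).
#'
#' @param series a segmented [patient_series()].
#' @param pairing `"consecutive"` or `"baseline"`.
#' @param dead_band_cho,dead_band_ratio passed to [classify_interval()].
#' @return List with `calls` (data.frame of per-interval summaries and
#'   labels) and `difference_maps` (list of per-pair `CHO` and
#'   `CHO_NAA_RATIO` [difference_map()]s).
#' @export
series_progression <- function(series, pairing = c("consecutive", "baseline"),
                               dead_band_cho = 0.05, dead_band_ratio = 0.1) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(series, "patient_series"))
  n <- length(series$timepoints)
  pairs <- if (pairing == "consecutive") {
    cbind(1:(n - 1), 2:n)
  } else {
    cbind(series$pre_index, setdiff(seq_len(n), series$pre_index))
  }
  calls <- list(); dmaps <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    tpe <- series$timepoints[[i]]; tpl <- series$timepoints[[j]]
    if (is.null(tpe$ratio) || is.null(tpl$ratio))
      stop("timepoints must be segmented before progression analysis",
           call. = FALSE)
    pair_ids <- sprintf("m%+g", c(tpe$months_from_rt, tpl$months_from_rt))
    mc_cho <- coverage_match(tpe$cho, tpl$cho)
    mc_ratio <- coverage_match(tpe$ratio, tpl$ratio)
    dm_cho <- difference_map(mc_cho[[1]], mc_cho[[2]], pair_ids)
    dm_ratio <- difference_map(mc_ratio[[1]], mc_ratio[[2]], pair_ids)
    roi_vals <- tpe$masks$CHO_NAA_2X$values | tpl$masks$CHO_NAA_2X$values
    if (!any(roi_vals))
      roi_vals <- (tpe$masks$GROUND_TRUTH %||% tpe$masks$CHO_NAA_2X)$values |
        (tpl$masks$GROUND_TRUTH %||% tpl$masks$CHO_NAA_2X)$values
    roi <- binary_mask(roi_vals, dm_cho$geometry, "GROUND_TRUTH")
    call <- classify_interval(dm_cho, dm_ratio, roi,
                              dead_band_cho, dead_band_ratio)
    calls[[r]] <- data.frame(
      patient = series$patient_id,
      earlier_months = tpe$months_from_rt,
      later_months = tpl$months_from_rt,
      delta_cho_median = call$delta_cho_summary,
      delta_ratio_median = call$delta_ratio_summary,
      roi_voxels = call$roi_voxels,
      dead_band_cho = dead_band_cho,
      dead_band_ratio = dead_band_ratio,
      label = call$label)
    dmaps[[paste(pair_ids, collapse = "_")]] <-
      list(cho = dm_cho, ratio = dm_ratio)
  }
  list(calls = do.call(rbind, calls), difference_maps = dmaps)
}

#' Orthogonal-slice plot of a difference map
#'
#' Basic inspection rendering: three orthogonal slices through a chosen
#' point, increases in red, decreases in blue, uncovered voxels grey.
#'
#' @param dm a [difference_map()].
#' @param center_voxel 1-based voxel index (length 3) of the crosshair;
#'   defaults to the voxel of largest absolute change.
#' @return Invisibly, `dm`.
#' @export
plot_difference_map <- function(dm, center_voxel = NULL) {
  stopifnot(inherits(dm, "difference_map"))
  v <- dm$values
  v[!dm$matched_coverage] <- NA
  if (is.null(center_voxel)) {
    center_voxel <- arrayInd(which.max(abs(ifelse(is.na(v), 0, v))), dim(v))
  }
  lim <- max(abs(v), na.rm = TRUE)
  if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
  old <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  slices <- list(v[center_voxel[1], , ], v[, center_voxel[2], ],
                 v[, , center_voxel[3]])
  titles <- c("sagittal", "coronal", "axial")
  for (s in 1:3) {
    graphics::image(slices[[s]], zlim = c(-lim, lim), col = pal,
                    axes = FALSE, main = titles[s], useRaster = TRUE)
  }
  invisible(dm)
}
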