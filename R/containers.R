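METABOLITE_KINDS <- c("CHO", "NAA", "CHO_NAA_RATIO")
MASK_LABELS <- c("CHO_NAA_2X", "FLAIR", "NAWM", "T1CE", "GROUND_TRUTH",
                 "BRAIN")

#' Metabolite map
#'
#' A 3D scalar field of one metabolite quantity (Cho, NAA, or the Cho/NAA
#' ratio) together with an explicit boolean coverage lattice marking voxels
#' where the spectroscopic fit produced valid data. Values are in arbitrary
#' institutional concentration units (the ratio is unitless); every covered
#' voxel must hold a finite value. Coverage is a companion lattice, not a
#' sentinel value, so "no data" is never confused with a concentration of
#' zero.
#'
#' @param values 3D numeric array.
#' @param coverage 3D logical array, same dim as `values`.
#' @param geometry a [grid_geometry()].
#' @param metabolite one of `"CHO"`, `"NAA"`, `"CHO_NAA_RATIO"`.
#' @return An object of class `metabolite_map`.
#' @export
metabolite_map <- function(values, coverage, geometry, metabolite) {
  metabolite <- match.arg(metabolite, METABOLITE_KINDS)
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("metabolite map values must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop("values dim does not match geometry shape", call. = FALSE)
  coverage <- array(as.logical(coverage), dim = dim(values))
  if (anyNA(coverage)) stop("coverage must be TRUE/FALSE", call. = FALSE)
  if (any(!is.finite(values[coverage])))
    stop("non-finite metabolite values inside coverage", call. = FALSE)
  structure(list(metabolite = metabolite, values = values,
                 coverage = coverage, geometry = geometry),
            class = "metabolite_map")
}

#' @export
print.metabolite_map <- function(x, ...) {
  cat(sprintf("metabolite_map <%s> on %s; %d/%d voxels covered\n",
              x$metabolite, format(x$geometry),
              sum(x$coverage), length(x$coverage)))
  invisible(x)
}

#' Binary mask
#'
#' A labeled 0/1 lattice on the common grid (tumor biomarker region, FLAIR
#' hyperintensity, NAWM reference, ground truth, ...).
#'
#' @param values 3D logical (or strictly 0/1 numeric) array.
#' @param geometry a [grid_geometry()].
#' @param label one of `"CHO_NAA_2X"`, `"FLAIR"`, `"NAWM"`, `"T1CE"`,
#'   `"GROUND_TRUTH"`, `"BRAIN"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, geometry, label) {
  label <- match.arg(label, MASK_LABELS)
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop("mask dim does not match geometry shape", call. = FALSE)
  if (is.numeric(values)) {
    if (any(!is.finite(values)) ||
        any(abs(values) > 1e-6 & abs(values - 1) > 1e-6))
      stop("mask values must be 0/1", call. = FALSE)
    values <- values > 0.5
  }
  values <- array(as.logical(values), dim = dim(values))
  if (anyNA(values)) stop("mask values must be 0/1", call. = FALSE)
  structure(list(label = label, values = values, geometry = geometry),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask <%s> on %s; %d voxels (%.3f cc)\n",
              x$label, format(x$geometry), sum(x$values), volume_cc(x)))
  invisible(x)
}

#' Mask volume in cubic centimeters
#'
#' Count of true voxels times the voxel volume. 1 cc = 1000 mm^3 = 1000 uL.
#' Additive over disjoint masks; an empty mask has volume 0.
#'
#' @param mask a [binary_mask()].
#' @return volume in cc.
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume_ul(mask$geometry) / 1000
}

#' One imaging timepoint of a patient series
#'
#' @param months_from_rt scan time in months relative to the end of
#'   radiotherapy (negative = pre-RT).
#' @param cho,naa [metabolite_map()]s (CHO and NAA).
#' @param masks named list of [binary_mask()]s keyed by label.
#' @return An object of class `timepoint`.
#' @export
timepoint <- function(months_from_rt, cho, naa, masks = list()) {
  stopifnot(is.numeric(months_from_rt), length(months_from_rt) == 1L,
            inherits(cho, "metabolite_map"), cho$metabolite == "CHO",
            inherits(naa, "metabolite_map"), naa$metabolite == "NAA")
  stop_if_geometry_mismatch(cho$geometry, naa$geometry)
  for (m in masks) {
    stopifnot(inherits(m, "binary_mask"))
    stop_if_geometry_mismatch(m$geometry, cho$geometry)
  }
  structure(list(months_from_rt = months_from_rt, cho = cho, naa = naa,
                 masks = masks),
            class = "timepoint")
}

#' Ordered longitudinal series of one patient
#'
#' Exactly one pre-RT (negative months) timepoint and at least one post-RT
#' timepoint, strictly increasing in time. The follow-up convention of the
#' underlying study is a pre-RT baseline, a first follow-up one month after
#' radiotherapy and further follow-ups every three months.
#'
#' @param patient_id character scalar.
#' @param timepoints list of [timepoint()]s, strictly increasing in
#'   `months_from_rt`.
#' @return An object of class `patient_series`.
#' @export
patient_series <- function(patient_id, timepoints) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            length(timepoints) >= 2L)
  months <- vapply(timepoints, function(tp) tp$months_from_rt, numeric(1))
  if (any(diff(months) <= 0))
    stop("timepoints must be strictly increasing in months_from_rt",
         call. = FALSE)
  n_pre <- sum(months < 0)
  if (n_pre != 1L)
    stop("series must contain exactly one pre-RT (negative months) ",
         "timepoint; found ", n_pre, call. = FALSE)
  if (sum(months >= 0) < 1L)
    stop("series must contain at least one post-RT timepoint",
         call. = FALSE)
  g <- timepoints[[1]]$cho$geometry
  for (tp in timepoints) stop_if_geometry_mismatch(tp$cho$geometry, g)
  structure(list(patient_id = patient_id, timepoints = timepoints,
                 months = months, pre_index = which(months < 0)),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("patient_series %s: %d timepoints at months [%s]\n",
              x$patient_id, length(x$timepoints),
              paste(x$months, collapse = ", ")))
  invisible(x)
}

series_months <- function(series)
  vapply(series$timepoints, function(tp) tp$months_from_rt, numeric(1))

post_indices <- function(series) which(series$months >= 0)
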