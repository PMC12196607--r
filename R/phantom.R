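#' Phantom configuration
#'
#' Defines a synthetic longitudinal head phantom: an ellipsoidal "brain" of
#' normal-appearing white matter (NAWM) metabolite levels containing a
#' spherical lesion with elevated choline and depressed NAA, so that the
#' lesion's Cho/NAA ratio is a chosen multiple of the NAWM ratio. Additive
#' Gaussian voxel noise (truncated at a small positive floor so ratios stay
#' defined), and a rind of missing spectroscopic coverage at the brain edge
#' emulate the limited coverage of whole-brain spectroscopic MRI.
#'
#' The lesion is placed off the mid-sagittal plane (first axis) so a
#' contralateral NAWM reference region exists on the opposite side.
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param voxel_spacing_mm 3 positive reals, mm.
#' @param brain_semi_axes_mm semi-axes of the brain ellipsoid, mm.
#' @param tumor_center_mm lesion center in mm (grid centered on 0).
#' @param tumor_radius_mm lesion radius, mm.
#' @param nawm_cho,nawm_naa NAWM metabolite levels, arbitrary institutional
#'   units.
#' @param tumor_ratio_multiple planted lesion Cho/NAA as a multiple of the
#'   NAWM Cho/NAA (> 1; >= 2 guarantees the lesion exceeds the 2X threshold
#'   in the noiseless limit). Realized as Cho raised by `sqrt(multiple)`
#'   and NAA lowered by the same factor.
#' @param noise_sd additive Gaussian noise SD per metabolite (same units as
#'   the concentrations).
#' @param coverage_erosion_mm width of the uncovered rind at the brain
#'   boundary, mm.
#' @param flair_margin_mm isotropic margin by which the FLAIR
#'   hyperintensity mask exceeds the metabolic lesion, mm (structural
#'   abnormality is broader than, and correlated with, the metabolic one).
#' @param seed integer seed; all phantom randomness derives from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           voxel_spacing_mm = c(3, 3, 3),
                           brain_semi_axes_mm = c(80, 90, 75),
                           tumor_center_mm = c(-35, 10, 5),
                           tumor_radius_mm = 18,
                           nawm_cho = 1.0,
                           nawm_naa = 1.0,
                           tumor_ratio_multiple = 3,
                           noise_sd = 0.1,
                           coverage_erosion_mm = 6,
                           flair_margin_mm = 4,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              brain_semi_axes_mm = as.numeric(brain_semi_axes_mm),
              tumor_center_mm = as.numeric(tumor_center_mm),
              tumor_radius_mm = tumor_radius_mm,
              nawm_cho = nawm_cho, nawm_naa = nawm_naa,
              tumor_ratio_multiple = tumor_ratio_multiple,
              noise_sd = noise_sd,
              coverage_erosion_mm = coverage_erosion_mm,
              flair_margin_mm = flair_margin_mm,
              seed = as.integer(seed))
  stopifnot(all(cfg$grid_shape > 0), all(cfg$voxel_spacing_mm > 0),
            all(cfg$brain_semi_axes_mm > 0), cfg$tumor_radius_mm > 0,
            cfg$nawm_cho > 0, cfg$nawm_naa > 0,
            cfg$tumor_ratio_multiple > 1, cfg$noise_sd >= 0,
            cfg$coverage_erosion_mm >= 0, cfg$flair_margin_mm >= 0)
  # lesion must fit inside the brain ellipsoid; conservative per-axis
  # bound: every sphere point x satisfies |x_i| <= |c_i| + r
  u <- abs(cfg$tumor_center_mm) + cfg$tumor_radius_mm
  if (sum((u / cfg$brain_semi_axes_mm)^2) > 1)
    stop("tumor sphere does not fit inside the brain ellipsoid ",
         "(center too peripheral or radius too large)", call. = FALSE)
  class(cfg) <- "phantom_config"
  cfg
}

#' Longitudinal evolution modes
#'
#' Per-timepoint multiplicative schedules for lesion radius, lesion Cho and
#' lesion NAA, applied geometrically per post-baseline step so a mode
#' extends to any number of timepoints:
#'
#' * `STABLE`: all multipliers 1.
#' * `RESPONSE`: lesion shrinks, Cho falls and NAA recovers, so the lesion
#'   Cho/NAA decays toward the NAWM value.
#' * `TRUE_PROGRESSION`: lesion grows, Cho rises and NAA falls, so both Cho
#'   and Cho/NAA strictly increase (the signature of active proliferation).
#' * `PSEUDOPROGRESSION`: Cho falls while NAA falls faster, so Cho/NAA
#'   rises despite the falling Cho (the paradoxical treatment-effect
#'   signature).
#'
#' @param label one of `"STABLE"`, `"RESPONSE"`, `"TRUE_PROGRESSION"`,
#'   `"PSEUDOPROGRESSION"`.
#' @return An object of class `evolution_mode` with per-step rate fields
#'   `radius_rate`, `cho_rate`, `naa_rate`.
#' @export
evolution_mode <- function(label) {
  label <- match.arg(label, c("STABLE", "RESPONSE", "TRUE_PROGRESSION",
                              "PSEUDOPROGRESSION"))
  rates <- switch(label,
    STABLE            = c(radius = 1.00, cho = 1.00, naa = 1.00),
    RESPONSE          = c(radius = 0.90, cho = 0.85, naa = 1.12),
    TRUE_PROGRESSION  = c(radius = 1.10, cho = 1.12, naa = 0.94),
    PSEUDOPROGRESSION = c(radius = 1.00, cho = 0.92, naa = 0.80))
  structure(list(label = label,
                 radius_rate = rates[["radius"]],
                 cho_rate = rates[["cho"]],
                 naa_rate = rates[["naa"]]),
            class = "evolution_mode")
}

mode_multipliers <- function(mode, step) {
  # step 0 = baseline
  c(radius = mode$radius_rate^step,
    cho = mode$cho_rate^step,
    naa = mode$naa_rate^step)
}

phantom_geometry <- function(config)
  grid_geometry(config$grid_shape, config$voxel_spacing_mm)

# mm coordinates of all voxel centers, n x 3
phantom_coords <- function(geom) voxel_to_mm(geom, all_voxel_indices(geom$shape))

ellipsoid_mask <- function(coords, center, semi_axes) {
  d <- sweep(coords, 2, center, `-`)
  rowSums(sweep(d, 2, semi_axes, `/`)^2) <= 1
}

sphere_mask <- function(coords, center, radius) {
  d <- sweep(coords, 2, center, `-`)
  rowSums(d^2) <= radius^2
}

#' Generate one phantom timepoint
#'
#' Rasterizes the analytic brain ellipsoid and lesion sphere by
#' voxel-center inclusion, fills Cho and NAA fields, adds truncated
#' Gaussian noise and assembles the companion masks:
#' ground-truth lesion, NAWM reference (lesion mirrored across the
#' mid-sagittal plane, restricted to brain and to the lesion's complement),
#' FLAIR (lesion dilated by `flair_margin_mm`), brain, and the
#' spectroscopic coverage lattice (brain eroded by `coverage_erosion_mm`,
#' computed analytically as the shrunken ellipsoid).
#'
#' @param config a [phantom_config()].
#' @param step nonnegative integer, position in the evolution schedule
#'   (0 = baseline).
#' @param mode an [evolution_mode()].
#' @param months_from_rt scan time in months relative to RT.
#' @param noise_stream integer; distinct timepoints of one series get
#'   distinct substreams of the config seed.
#' @return A [timepoint()] with masks `GROUND_TRUTH`, `NAWM`, `FLAIR`,
#'   `BRAIN`.
#' @export
make_timepoint <- function(config, step = 0L, mode = evolution_mode("STABLE"),
                           months_from_rt = -1, noise_stream = 0L) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(mode, "evolution_mode"), step >= 0)
  geom <- phantom_geometry(config)
  coords <- phantom_coords(geom)
  mult <- mode_multipliers(mode, step)

  brain <- ellipsoid_mask(coords, c(0, 0, 0), config$brain_semi_axes_mm)
  erode <- pmax(config$brain_semi_axes_mm - config$coverage_erosion_mm,
                .Machine$double.eps)
  coverage <- if (config$coverage_erosion_mm > 0)
    ellipsoid_mask(coords, c(0, 0, 0), erode) else brain

  radius <- config$tumor_radius_mm * mult[["radius"]]
  tumor <- sphere_mask(coords, config$tumor_center_mm, radius)
  flair <- sphere_mask(coords, config$tumor_center_mm,
                       radius + config$flair_margin_mm) & brain

  # reference region mirrored at the baseline radius: the NAWM reference
  # is a fixed tissue region, it does not track lesion evolution
  mirror_center <- config$tumor_center_mm * c(-1, 1, 1)
  nawm <- sphere_mask(coords, mirror_center, config$tumor_radius_mm) &
    brain & !tumor

  # lesion contrast: Cho up by sqrt(multiple), NAA down by sqrt(multiple),
  # then the mode's per-step multipliers on the lesion values only
  s <- sqrt(config$tumor_ratio_multiple)
  cho_vals <- rep(config$nawm_cho, nrow(coords))
  naa_vals <- rep(config$nawm_naa, nrow(coords))
  cho_vals[tumor] <- config$nawm_cho * s * mult[["cho"]]
  naa_vals[tumor] <- config$nawm_naa / s * mult[["naa"]]

  if (config$noise_sd > 0) {
    substream <- (as.numeric(config$seed) * 1009 +
                    as.numeric(noise_stream)) %% 2147483647
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(substream)
    floor_val <- 1e-3 * min(config$nawm_cho, config$nawm_naa)
    cho_vals <- pmax(cho_vals + stats::rnorm(length(cho_vals), 0, config$noise_sd),
                     floor_val)
    naa_vals <- pmax(naa_vals + stats::rnorm(length(naa_vals), 0, config$noise_sd),
                     floor_val)
  }
  cho_vals[!coverage] <- 0
  naa_vals[!coverage] <- 0

  to_arr <- function(v) array(v, dim = geom$shape)
  cov_arr <- to_arr(coverage)
  timepoint(
    months_from_rt = months_from_rt,
    cho = metabolite_map(to_arr(cho_vals), cov_arr, geom, "CHO"),
    naa = metabolite_map(to_arr(naa_vals), cov_arr, geom, "NAA"),
    masks = list(
      GROUND_TRUTH = binary_mask(to_arr(tumor), geom, "GROUND_TRUTH"),
      NAWM = binary_mask(to_arr(nawm), geom, "NAWM"),
      FLAIR = binary_mask(to_arr(flair), geom, "FLAIR"),
      BRAIN = binary_mask(to_arr(brain), geom, "BRAIN")))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a longitudinal phantom series
#'
#' One timepoint per entry of `timepoints_months` (exactly one pre-RT,
#' i.e. negative, entry required; strictly increasing), following the
#' mode's per-step schedules. The default grid mirrors the study's
#' follow-up schedule: baseline one month before RT, first follow-up one
#' month post-RT, then every three months.
#'
#' @param config a [phantom_config()].
#' @param mode an [evolution_mode()] or its label.
#' @param timepoints_months numeric vector of months from RT.
#' @param patient_id identifier for the series.
#' @return A [patient_series()] with ground-truth masks retained.
#' @export
make_series <- function(config, mode = evolution_mode("STABLE"),
                        timepoints_months = c(-1, 1, 4, 7, 10),
                        patient_id = "phantom") {
  if (is.character(mode)) mode <- evolution_mode(mode)
  if (any(diff(timepoints_months) <= 0))
    stop("timepoints_months must be strictly increasing", call. = FALSE)
  if (sum(timepoints_months < 0) != 1L)
    stop("need exactly one pre-RT (negative) timepoint", call. = FALSE)
  tps <- lapply(seq_along(timepoints_months), function(i) {
    make_timepoint(config, step = i - 1L, mode = mode,
                   months_from_rt = timepoints_months[i],
                   noise_stream = i - 1L)
  })
  patient_series(patient_id, tps)
}

#' Simulate a phantom cohort
#'
#' @param n_patients number of series.
#' @param mode an [evolution_mode()] label, recycled over patients, or a
#'   vector of labels (one per patient).
#' @param config base [phantom_config()]; each patient p gets seed
#'   `config$seed + p`.
#' @param timepoints_months shared scan schedule.
#' @return List of [patient_series()].
#' @export
simulate_cohort <- function(n_patients = 6,
                            mode = c("STABLE", "RESPONSE",
                                     "TRUE_PROGRESSION",
                                     "PSEUDOPROGRESSION"),
                            config = phantom_config(),
                            timepoints_months = c(-1, 1, 4, 7, 10)) {
  modes <- rep_len(mode, n_patients)
  lapply(seq_len(n_patients), function(p) {
    cfg <- config
    cfg$seed <- (config$seed + p) %% .Machine$integer.max
    make_series(cfg, modes[p], timepoints_months,
                patient_id = sprintf("PHANTOM%03d", p))
  })
}

#' Write a phantom cohort to disk with a manifest
#'
#' Writes every metabolite map and mask as NIfTI under
#' `out_dir/<patient>/tp<k>_...` and a YAML manifest binding file roles to
#' paths with months_from_rt per timepoint.
#'
#' @param cohort list of [patient_series()].
#' @param out_dir output directory (created).
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, out_dir, compress = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  manifest <- list(patients = list())
  for (series in cohort) {
    pdir <- file.path(out_dir, series$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    tps <- list()
    for (i in seq_along(series$timepoints)) {
      tp <- series$timepoints[[i]]
      stem <- file.path(pdir, sprintf("tp%02d", i))
      files <- list(cho = paste0(stem, "_cho", ext),
                    naa = paste0(stem, "_naa", ext))
      write_volume(tp$cho, files$cho)
      write_volume(tp$naa, files$naa)
      for (lbl in names(tp$masks)) {
        f <- paste0(stem, "_", tolower(lbl), ext)
        write_volume(tp$masks[[lbl]], f)
        files[[tolower(lbl)]] <- f
      }
      tps[[i]] <- list(months_from_rt = tp$months_from_rt, files = files)
    }
    manifest$patients[[series$patient_id]] <-
      list(id = series$patient_id, timepoints = tps)
  }
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path path to the YAML manifest written by
#'   [write_cohort()].
#' @return List of [patient_series()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(manifest$patients, function(pat) {
    tps <- lapply(pat$timepoints, function(tp) {
      f <- tp$files
      cho <- read_volume(resolve(f$cho), "CHO")
      naa <- read_volume(resolve(f$naa), "NAA")
      mask_roles <- setdiff(names(f), c("cho", "naa"))
      masks <- list()
      for (r in mask_roles) {
        lbl <- toupper(r)
        if (lbl %in% MASK_LABELS)
          masks[[lbl]] <- read_volume(resolve(f[[r]]), "mask", label = lbl)
      }
      timepoint(tp$months_from_rt, cho, naa, masks)
    })
    patient_series(pat$id, tps)
  })
}
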