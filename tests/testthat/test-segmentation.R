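make_pair <- function(cho_vals, naa_vals, cov_cho = NULL, cov_naa = NULL,
                      shape = c(4, 4, 2)) {
  geom <- grid_geometry(shape, c(2, 2, 2))
  if (is.null(cov_cho)) cov_cho <- array(TRUE, dim = shape)
  if (is.null(cov_naa)) cov_naa <- array(TRUE, dim = shape)
  cho <- array(cho_vals, dim = shape); cho[!cov_cho] <- 0
  naa <- array(naa_vals, dim = shape); naa[!cov_naa] <- 0
  list(cho = metabolite_map(cho, cov_cho, geom, "CHO"),
       naa = metabolite_map(naa, cov_naa, geom, "NAA"))
}

test_that("ratio_map divides voxelwise on the coverage intersection", {
  p <- make_pair(2.0, 1.0)
  r <- ratio_map(p$cho, p$naa)
  expect_true(all(abs(r$values[r$coverage] - 2.0) < 1e-12))

  # NAA of zero excludes the voxel instead of producing an infinite ratio
  naa <- array(1, dim = c(4, 4, 2)); naa[1, 1, 1] <- 0
  p2 <- make_pair(2.0, naa)
  r2 <- ratio_map(p2$cho, p2$naa)
  expect_false(r2$coverage[1, 1, 1])
  expect_true(all(r2$coverage[-1]))

  # a voxel covered in Cho only is excluded
  cov_naa <- array(TRUE, dim = c(4, 4, 2)); cov_naa[2, 2, 1] <- FALSE
  p3 <- make_pair(2.0, 1.0, cov_naa = cov_naa)
  r3 <- ratio_map(p3$cho, p3$naa)
  expect_false(r3$coverage[2, 2, 1])

  other <- uniform_map(1, shape = c(5, 5, 5), metabolite = "NAA")
  expect_error(ratio_map(p$cho, other), "same grid")
})

test_that("the NAWM reference is the arithmetic mean over the region", {
  shape <- c(5, 5, 4)
  geom <- grid_geometry(shape, c(2, 2, 2))
  vals <- array(1.0, dim = shape)
  # plant {0.8, 1.0, 1.2} repeated over a 60-voxel region
  region <- array(FALSE, dim = shape); region[1:60] <- TRUE
  vals[1:60] <- rep(c(0.8, 1.0, 1.2), 20)
  r <- metabolite_map(vals, array(TRUE, dim = shape), geom, "CHO_NAA_RATIO")
  ref <- nawm_reference(r, binary_mask(region, geom, "NAWM"))
  expect_equal(ref$mean_ratio, 1.0)
  expect_equal(ref$n_voxels, 60L)

  tiny <- array(FALSE, dim = shape); tiny[1:10] <- TRUE
  expect_error(nawm_reference(r, binary_mask(tiny, geom, "NAWM")),
               "50 required")
  none <- array(FALSE, dim = shape)
  expect_error(nawm_reference(r, binary_mask(none, geom, "NAWM")))
})

test_that("mirror_nawm reflects across the mid-sagittal plane", {
  shape <- c(10, 6, 6)
  brain <- array(TRUE, dim = shape)
  lesion <- array(FALSE, dim = shape)
  lesion[2:4, 2:4, 2:4] <- TRUE
  m <- mirror_nawm(mask_from_array(lesion), mask_from_array(brain, label = "BRAIN"))
  expect_equal(sum(m$values), sum(lesion))
  idx <- arrayInd(which(m$values), shape)
  expect_true(all(idx[, 1] >= 7))  # strictly the other hemisphere

  # midline lesion overlapping its own mirror loses the overlap voxels
  mid <- array(FALSE, dim = shape)
  mid[4:7, 3, 3] <- TRUE  # symmetric around the center plane
  expect_error(mirror_nawm(mask_from_array(mid),
                           mask_from_array(brain, label = "BRAIN")),
               "empty")
  partial <- array(FALSE, dim = shape)
  partial[3:6, 3, 3] <- TRUE  # mirror is 5:8; overlap 5:6 removed
  m2 <- mirror_nawm(mask_from_array(partial),
                    mask_from_array(brain, label = "BRAIN"))
  expect_equal(sort(arrayInd(which(m2$values), shape)[, 1]), c(7, 8))

  empty <- array(FALSE, dim = shape)
  expect_error(mirror_nawm(mask_from_array(empty),
                           mask_from_array(brain, label = "BRAIN")),
               "lesion mask is empty")
})

test_that("the 2X threshold is inclusive and respects coverage", {
  shape <- c(6, 6, 4)
  geom <- grid_geometry(shape, c(2, 2, 2))
  vals <- array(1.0, dim = shape)
  vals[1, 1, 1] <- 2.0   # exactly at threshold -> included
  vals[2, 1, 1] <- 1.999
  vals[3, 1, 1] <- 5.0   # above threshold but uncovered
  cov <- array(TRUE, dim = shape); cov[3, 1, 1] <- FALSE
  vals[3, 1, 1] <- 0
  r <- metabolite_map(vals, cov, geom, "CHO_NAA_RATIO")
  ref <- structure(list(mean_ratio = 1.0, n_voxels = 100,
                        source = "MANUAL_MASK", stat = "mean"),
                   class = "nawm_reference")
  m <- threshold_mask(r, ref, factor = 2, min_component_cc = 0)
  expect_true(m$values[1, 1, 1])
  expect_false(m$values[2, 1, 1])
  expect_false(m$values[3, 1, 1])
  expect_equal(sum(m$values), 1L)

  all_low <- metabolite_map(array(1, dim = shape), array(TRUE, dim = shape),
                            geom, "CHO_NAA_RATIO")
  expect_equal(sum(threshold_mask(all_low, ref, 2, 0)$values), 0L)
})

test_that("threshold_mask is monotone in the threshold factor", {
  tp <- make_timepoint(small_config(noise_sd = 0.2, seed = 13))
  r <- ratio_map(tp$cho, tp$naa)
  ref <- nawm_reference(r, tp$masks$NAWM)
  prev <- threshold_mask(r, ref, 1.2, 0)
  for (f in c(1.5, 2.0, 2.5, 3.0)) {
    cur <- threshold_mask(r, ref, f, 0)
    expect_true(all(cur$values <= prev$values))
    prev <- cur
  }
})

test_that("the ratio biomarker is invariant under common intensity rescaling", {
  tp <- make_timepoint(small_config(noise_sd = 0.1, seed = 31))
  seg1 <- segment_timepoint(tp, min_component_cc = 0)
  scaled <- tp
  scale_map <- function(m, k) {
    v <- m$values * k
    metabolite_map(v, m$coverage, m$geometry, m$metabolite)
  }
  scaled$cho <- scale_map(tp$cho, 7.3)
  scaled$naa <- scale_map(tp$naa, 7.3)
  seg2 <- segment_timepoint(scaled, min_component_cc = 0)
  expect_identical(seg1$masks$CHO_NAA_2X$values, seg2$masks$CHO_NAA_2X$values)
  expect_equal(seg1$nawm_ref$mean_ratio, seg2$nawm_ref$mean_ratio)
})

test_that("noiseless segmentation recovers the planted lesion exactly", {
  tp <- make_timepoint(small_config(noise_sd = 0, tumor_ratio_multiple = 3))
  seg <- segment_timepoint(tp, min_component_cc = 0)
  expect_identical(seg$masks$CHO_NAA_2X$values, tp$masks$GROUND_TRUTH$values)
})

test_that("the component size filter removes specks and keeps the lesion", {
  shape <- c(12, 12, 8)
  geom <- grid_geometry(shape, c(2, 2, 2))  # voxel = 8 uL
  arr <- array(FALSE, dim = shape)
  arr[3:6, 3:6, 3:5] <- TRUE    # 48 voxels = 0.384 cc
  arr[10, 10, 7] <- TRUE        # 1 voxel = 0.008 cc speck
  arr[10, 11, 8] <- TRUE        # diagonal neighbour: same 26-component
  m <- binary_mask(arr, geom, "CHO_NAA_2X")
  f <- filter_small_components(m, min_cc = 0.1)
  expect_equal(sum(f$values), 48L)
  expect_false(f$values[10, 10, 7])
  # with 6-connectivity the two speck voxels are separate components too
  f6 <- filter_small_components(m, min_cc = 0.01, connectivity = 6)
  expect_equal(sum(f6$values), 48L)
  f26 <- filter_small_components(m, min_cc = 0.01, connectivity = 26)
  expect_equal(sum(f26$values), 50L)  # 2-voxel component = 0.016 cc kept
})

test_that("segmentation never includes voxels outside ratio coverage", {
  tp <- make_timepoint(small_config(noise_sd = 0.3, seed = 77))
  seg <- segment_timepoint(tp, min_component_cc = 0)
  r <- ratio_map(tp$cho, tp$naa)
  expect_true(all(!seg$masks$CHO_NAA_2X$values | r$coverage))
})
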