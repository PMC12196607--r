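test_that("coverage matching excludes one-sided voxels from both maps", {
  shape <- c(5, 5, 4)
  cov1 <- array(TRUE, dim = shape); cov1[1, 1, 1] <- FALSE
  cov2 <- array(TRUE, dim = shape); cov2[5, 5, 4] <- FALSE
  m1 <- uniform_map(1.0, shape = shape, coverage = cov1)
  m2 <- uniform_map(1.5, shape = shape, coverage = cov2)
  mc <- coverage_match(m1, m2)
  expect_identical(mc[[1]]$coverage, mc[[2]]$coverage)
  expect_false(mc[[1]]$coverage[1, 1, 1])
  expect_false(mc[[1]]$coverage[5, 5, 4])
  expect_equal(sum(mc[[1]]$coverage), prod(shape) - 2)

  # identical coverage: outputs equal inputs
  mc2 <- coverage_match(m1, uniform_map(2, shape = shape, coverage = cov1))
  expect_equal(mc2[[1]]$values, m1$values)

  cov3 <- array(FALSE, dim = shape)
  cov3[1, 1, 1] <- TRUE
  cov4 <- array(FALSE, dim = shape); cov4[2, 1, 1] <- TRUE
  expect_error(coverage_match(uniform_map(1, shape = shape, coverage = cov3),
                              uniform_map(1, shape = shape, coverage = cov4)),
               "empty")
})

test_that("difference maps are signed later-minus-earlier and antisymmetric", {
  shape <- c(5, 5, 4)
  m1 <- uniform_map(1.0, shape = shape)
  m2 <- uniform_map(1.5, shape = shape)
  dm <- difference_map(m1, m2)
  expect_true(all(abs(dm$values[dm$matched_coverage] - 0.5) < 1e-12))
  dm_rev <- difference_map(m2, m1)
  expect_equal(dm_rev$values, -dm$values)
  expect_equal(difference_map(m1, m1)$values, array(0, dim = shape))

  # unmatched coverage is rejected
  cov <- array(TRUE, dim = shape); cov[1, 1, 1] <- FALSE
  m3 <- uniform_map(2, shape = shape, coverage = cov)
  expect_error(difference_map(m1, m3), "coverage_match")
})

test_that("consecutive difference maps telescope", {
  cfg <- small_config(noise_sd = 0.1, seed = 4)
  t1 <- make_timepoint(cfg, noise_stream = 1)
  t2 <- make_timepoint(cfg, noise_stream = 2)
  t3 <- make_timepoint(cfg, noise_stream = 3)
  m12 <- coverage_match(t1$cho, t2$cho)
  m23 <- coverage_match(t2$cho, t3$cho)
  m13 <- coverage_match(t1$cho, t3$cho)
  d12 <- difference_map(m12[[1]], m12[[2]])$values
  d23 <- difference_map(m23[[1]], m23[[2]])$values
  d13 <- difference_map(m13[[1]], m13[[2]])$values
  triple <- t1$cho$coverage & t2$cho$coverage & t3$cho$coverage
  expect_true(all(abs((d12 + d23 - d13)[triple]) < 1e-12))
})

test_that("volume trajectories report percent change from the previous scan", {
  geom <- grid_geometry(c(20, 20, 10), c(5, 5, 10))  # voxel = 0.25 cc
  mk <- function(n) {
    arr <- array(FALSE, dim = c(20, 20, 10))
    if (n > 0) arr[seq_len(n)] <- TRUE
    binary_mask(arr, geom, "FLAIR")
  }
  mk_tp <- function(months, n_vox) {
    cov <- array(TRUE, dim = c(20, 20, 10))
    tp <- timepoint(months,
                    metabolite_map(array(1, dim = c(20, 20, 10)), cov, geom, "CHO"),
                    metabolite_map(array(1, dim = c(20, 20, 10)), cov, geom, "NAA"),
                    masks = list(FLAIR = mk(n_vox)))
    tp
  }
  # 100 cc -> 150 cc -> 60 cc: +50 %, -60 %
  s <- patient_series("T", list(mk_tp(-1, 400), mk_tp(1, 600), mk_tp(4, 240)))
  traj <- volume_trajectory(s, "FLAIR")
  expect_equal(traj$volume_cc, c(100, 150, 60))
  expect_equal(traj$percent_change, c(NA, 50, -60))

  # 80 -> 60 is -25 %
  s2 <- patient_series("T2", list(mk_tp(-1, 320), mk_tp(1, 240)))
  expect_equal(volume_trajectory(s2, "FLAIR")$percent_change[2], -25)

  # zero previous volume -> undefined, flagged
  s3 <- patient_series("T3", list(mk_tp(-1, 0), mk_tp(1, 100)))
  traj3 <- volume_trajectory(s3, "FLAIR")
  expect_true(is.na(traj3$percent_change[2]))
  expect_match(traj3$flags[2], "zero_previous")
})

test_that("interval classification follows the concurrent-change rule", {
  shape <- c(6, 6, 4)
  roi <- mask_from_array(array(TRUE, dim = shape))
  mk_dm <- function(delta, metab) {
    m1 <- uniform_map(2.0, shape = shape, spacing = c(1, 1, 1),
                      metabolite = metab)
    m2 <- uniform_map(2.0 + delta, shape = shape, spacing = c(1, 1, 1),
                      metabolite = metab)
    difference_map(m1, m2, pair = c("t1", "t2"))
  }
  call1 <- classify_interval(mk_dm(0.3, "CHO"), mk_dm(0.5, "CHO_NAA_RATIO"),
                             roi, 0.05, 0.05)
  expect_equal(call1$label, "TRUE_PROGRESSION")
  call2 <- classify_interval(mk_dm(-0.3, "CHO"), mk_dm(0.5, "CHO_NAA_RATIO"),
                             roi, 0.05, 0.05)
  expect_equal(call2$label, "PSEUDOPROGRESSION")
  call3 <- classify_interval(mk_dm(0.02, "CHO"), mk_dm(-0.01, "CHO_NAA_RATIO"),
                             roi, 0.05, 0.05)
  expect_equal(call3$label, "STABLE_OR_RESPONSE")
  # a ratio rise inside the dead band is not progression
  call4 <- classify_interval(mk_dm(0.3, "CHO"), mk_dm(0.04, "CHO_NAA_RATIO"),
                             roi, 0.05, 0.05)
  expect_equal(call4$label, "STABLE_OR_RESPONSE")

  empty_roi <- mask_from_array(array(FALSE, dim = shape))
  expect_error(classify_interval(mk_dm(0.3, "CHO"),
                                 mk_dm(0.5, "CHO_NAA_RATIO"),
                                 empty_roi, 0.05, 0.05),
               "ROI")
})

test_that("series_progression recovers each planted mode end to end", {
  for (mode in c("STABLE", "TRUE_PROGRESSION", "PSEUDOPROGRESSION",
                 "RESPONSE")) {
    s <- make_series(small_config(noise_sd = 0.05, seed = 17), mode,
                     timepoints_months = c(-1, 1, 4))
    s$timepoints <- lapply(s$timepoints, segment_timepoint)
    out <- series_progression(s)
    expected <- switch(mode,
                       STABLE = "STABLE_OR_RESPONSE",
                       RESPONSE = "STABLE_OR_RESPONSE",
                       mode)
    expect_true(all(out$calls$label == expected),
                label = paste("mode", mode))
    expect_equal(nrow(out$calls), 2L)
  }
})

test_that("baseline-anchored pairing compares every post scan to pre-RT", {
  s <- make_series(small_config(noise_sd = 0), "TRUE_PROGRESSION")
  s$timepoints <- lapply(s$timepoints, segment_timepoint)
  out <- series_progression(s, pairing = "baseline")
  expect_equal(nrow(out$calls), 4L)
  expect_true(all(out$calls$earlier_months == -1))
  expect_true(all(out$calls$label == "TRUE_PROGRESSION"))
})
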