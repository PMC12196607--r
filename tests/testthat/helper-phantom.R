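# Small phantom configuration used across tests: coarse 4 mm grid keeps
# every Monte-Carlo stage fast while leaving enough lesion voxels (~60)
# for stable medians and overlap metrics.
small_config <- function(noise_sd = 0, seed = 1L, ...) {
  args <- list(grid_shape = c(28, 28, 20), voxel_spacing_mm = c(4, 4, 4),
               brain_semi_axes_mm = c(48, 48, 34),
               tumor_center_mm = c(-20, 4, 2), tumor_radius_mm = 10,
               noise_sd = noise_sd, coverage_erosion_mm = 4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

# binary mask on a simple unit grid from a logical array
mask_from_array <- function(arr, spacing = c(1, 1, 1), label = "GROUND_TRUTH") {
  geom <- grid_geometry(dim(arr), spacing)
  binary_mask(arr, geom, label)
}

# random mask of given density on a grid (logical array)
random_mask_array <- function(shape, density = 0.15) {
  array(stats::runif(prod(shape)) < density, dim = shape)
}

# uniform metabolite map helper
uniform_map <- function(value, shape = c(6, 6, 4), spacing = c(2, 2, 2),
                        metabolite = "CHO", coverage = NULL) {
  geom <- grid_geometry(shape, spacing)
  if (is.null(coverage)) coverage <- array(TRUE, dim = shape)
  vals <- array(value, dim = shape)
  vals[!coverage] <- 0
  metabolite_map(vals, coverage, geom, metabolite)
}

# Independent boundary extraction: per-voxel loop over the 6 face
# neighbours (used as an oracle against the vectorized implementation).
boundary_oracle <- function(arr) {
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!arr[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (n in nb) {
      if (any(n < 1) || n[1] > d[1] || n[2] > d[2] || n[3] > d[3] ||
          !arr[n[1], n[2], n[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# Exhaustive max-min Hausdorff oracle over two point sets (mm)
hausdorff_oracle_points <- function(pa, pb) {
  dmat <- as.matrix(stats::dist(rbind(pa, pb)))
  na <- nrow(pa)
  cross <- dmat[seq_len(na), na + seq_len(nrow(pb)), drop = FALSE]
  max(max(apply(cross, 1, min)), max(apply(cross, 2, min)))
}

# Exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
wilcoxon_enumeration_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}
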