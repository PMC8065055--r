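# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data.

# A reproducible random rigid transform with rotation up to max_angle
# (radians) and translation up to max_trans (mm).
random_rigid <- function(seed, source = "A", target = "B",
                         max_angle = pi, max_trans = 100) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- rotation_matrix(ax, runif(1, -max_angle, max_angle))
  transform_rigid(R, runif(3, -max_trans, max_trans), source, target)
}

# A well-conditioned non-coplanar fiducial cloud.
random_fiducials <- function(seed, n = 7, frame = "tank", scale = 60) {
  set.seed(seed)
  fiducial_set(matrix(runif(n * 3, -scale, scale), n, 3), frame)
}

# Binary sphere mask on an isotropic grid (analytic construction).
sphere_mask <- function(center, radius, spacing, lo, hi, frame = "world") {
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  grid <- volume_image(array(0, dims), rep(spacing, 3), lo, frame = frame)
  ctr <- voxel_centers(grid)
  inside <- sqrt(rowSums(sweep(ctr, 2, center)^2)) <= radius
  label_mask(array(inside, dims), rep(spacing, 3), lo, frame = frame)
}

# Small quantized test volume whose intensities sit exactly on histogram
# bin centres (so partial-volume weighting reduces to hard binning).
quantized_volume <- function(seed, dims = c(16, 16, 16), bins = 32,
                             frame = "world") {
  set.seed(seed)
  vox <- array(sample.int(bins, prod(dims), replace = TRUE) - 1L, dims)
  volume_image(vox, frame = frame)
}
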