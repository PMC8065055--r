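test_that("dice matches identity, disjointness and the lens-volume oracle", {
  s1 <- sphere_mask(c(0, 0, 0), 5, 0.4, lo = c(-8, -8, -8), hi = c(10, 8, 8))
  expect_equal(dice(s1, s1), 1.0)
  s_far <- sphere_mask(c(0, 0, 0) + c(12, 0, 0), 2, 0.4,
                       lo = c(-8, -8, -8), hi = c(10, 8, 8))
  expect_equal(dice(s1, s_far), 0.0)

  # equal spheres r = 5 offset d = 2: lens volume pi (4r + d)(2r - d)^2 / 12
  s2 <- sphere_mask(c(2, 0, 0), 5, 0.4, lo = c(-8, -8, -8), hi = c(10, 8, 8))
  lens <- pi * (4 * 5 + 2) * (2 * 5 - 2)^2 / 12
  vol <- 4 / 3 * pi * 5^3
  expect_equal(dice(s1, s2), 2 * lens / (2 * vol), tolerance = 0.01)
  expect_equal(dice(s1, s2), dice(s2, s1))

  empty <- label_mask(array(0, dim(s1$voxels)), s1$spacing, s1$origin,
                      frame = s1$frame)
  expect_error(dice(empty, empty), "undefined|empty")
})

test_that("hausdorff and mean boundary distance follow geometric oracles", {
  # single voxels 3 voxels apart on a 1 mm grid
  a <- array(0, c(8, 8, 8)); a[2, 2, 2] <- 1
  b <- array(0, c(8, 8, 8)); b[5, 2, 2] <- 1
  ma <- label_mask(a); mb <- label_mask(b)
  expect_equal(hausdorff(ma, mb), 3.0)
  expect_equal(as.numeric(mean_boundary_distance(ma, mb)), 3.0)
  expect_equal(hausdorff(ma, ma), 0.0)
  expect_equal(as.numeric(mean_boundary_distance(ma, ma)), 0.0)

  # equal spheres offset 2 mm: Hausdorff = 2 within grid tolerance
  s1 <- sphere_mask(c(0, 0, 0), 5, 0.4, lo = c(-8, -8, -8), hi = c(10, 8, 8))
  s2 <- sphere_mask(c(2, 0, 0), 5, 0.4, lo = c(-8, -8, -8), hi = c(10, 8, 8))
  expect_equal(hausdorff(s1, s2), 2.0, tolerance = 0.4)
  mbd <- mean_boundary_distance(s1, s2)
  expect_lte(as.numeric(mbd), 2.0)                   # bounded by the offset
  expect_lte(as.numeric(mbd), hausdorff(s1, s2))     # ordering invariant

  # implementation agrees with the independent all-pairs oracle
  expect_equal(as.numeric(mbd), mbd_oracle(s1, s2), tolerance = 1e-6)

  expect_error(hausdorff(s1, label_mask(array(0, dim(s1$voxels)),
                                        s1$spacing, s1$origin)),
               "empty")
})

test_that("surface metrics are symmetric and translation-invariant", {
  set.seed(8)
  blob <- array(0, c(20, 20, 20))
  blob[5:12, 6:14, 4:11] <- 1
  blob[10:16, 3:9, 9:15] <- 1
  a <- label_mask(blob, spacing = c(0.7, 0.7, 0.7))
  blob2 <- array(0, c(20, 20, 20))
  blob2[7:13, 5:12, 6:13] <- 1
  b <- label_mask(blob2, spacing = c(0.7, 0.7, 0.7))

  expect_equal(hausdorff(a, b), hausdorff(b, a))
  expect_equal(as.numeric(mean_boundary_distance(a, b)),
               as.numeric(mean_boundary_distance(b, a)))
  expect_gte(hausdorff(a, b), as.numeric(mean_boundary_distance(a, b)))

  # common integer-voxel translation changes nothing
  sh <- function(x) {
    y <- array(0, dim(x)); y[3:20, 2:20, 1:19] <- x[1:18, 1:19, 2:20]; y
  }
  a2 <- label_mask(sh(blob), spacing = c(0.7, 0.7, 0.7))
  b2 <- label_mask(sh(blob2), spacing = c(0.7, 0.7, 0.7))
  expect_equal(dice(a2, b2), dice(a, b))
  expect_equal(hausdorff(a2, b2), hausdorff(a, b))
  expect_equal(as.numeric(mean_boundary_distance(a2, b2)),
               as.numeric(mean_boundary_distance(a, b)))
})

test_that("lesion centroid TRE measures per-label displacement", {
  s <- sphere_mask(c(0, 0, 0), 4, 0.5, lo = c(-6, -6, -6), hi = c(10, 6, 6))
  expect_equal(lesion_centroid_tre(list(l1 = s), list(l1 = s))$mean_mm, 0)

  s_sh <- sphere_mask(c(2, 0, 0), 4, 0.5, lo = c(-6, -6, -6), hi = c(10, 6, 6))
  expect_equal(lesion_centroid_tre(list(l1 = s), list(l1 = s_sh))$mean_mm,
               2.0, tolerance = 0.05)
  expect_error(lesion_centroid_tre(list(a = s), list(b = s)), "labels")

  # three rendered lesions under the true affine come back sub-voxel
  ph <- render_phantom(phantom_spec(), "mr", spacing = 1)
  t <- random_rigid(71, "MR", "US", max_angle = 0.3, max_trans = 10)
  moved <- lapply(ph$lesion_masks, function(m) {
    grid <- volume_image(array(0, dim(m$voxels) + 20L), m$spacing,
                         m$origin - 10, frame = "US")
    resample_volume(m, grid, t)
  })
  tre <- lesion_centroid_tre(ph$lesion_masks, moved, t)
  expect_lt(max(tre$per_lesion_mm), 0.5)
})

test_that("psnr follows its closed forms", {
  v <- volume_image(array(runif(1000, 0, 10), c(10, 10, 10)))
  same <- psnr(v, v)
  expect_true(is.infinite(same))
  expect_true(attr(same, "identical"))

  # MSE == peak^2 gives exactly 0 dB
  a <- volume_image(array(0, c(5, 5, 5)))
  b <- volume_image(array(3, c(5, 5, 5)))
  expect_equal(psnr(a, b, peak = 3), 0)

  # constant offset c on a range peak: 20 log10(peak / c)
  off <- v; off$voxels <- v$voxels + 0.5
  expect_equal(psnr(v, off, peak = 10), 20 * log10(10 / 0.5),
               tolerance = 1e-9)

  # additive gaussian noise: PSNR ~ 20 log10(peak / sigma)
  set.seed(9)
  big <- volume_image(array(runif(60^3, 0, 100), c(60, 60, 60)))
  noisy <- big; noisy$voxels <- big$voxels + rnorm(60^3, sd = 4)
  expect_equal(psnr(big, noisy, peak = 100), 20 * log10(100 / 4),
               tolerance = 0.01)
  expect_error(psnr(big, noisy, peak = -1), "positive")
})

test_that("overlap_report combines the metrics and resamples when needed", {
  s1 <- sphere_mask(c(0, 0, 0), 5, 0.5, lo = c(-8, -8, -8), hi = c(10, 8, 8))
  s2 <- sphere_mask(c(2, 0, 0), 5, 0.5, lo = c(-8, -8, -8), hi = c(10, 8, 8))
  rep <- overlap_report(s1, s2)
  expect_s3_class(rep, "overlap_report")
  expect_false(rep$resampled)
  expect_equal(rep$dice, dice(s1, s2))
  expect_gte(rep$hausdorff_mm, rep$mean_boundary_distance_mm)

  # same physical mask on a finer grid: near-perfect overlap after
  # nearest-neighbour resampling
  s2_fine <- sphere_mask(c(0, 0, 0), 5, 0.25, lo = c(-8, -8, -8),
                         hi = c(10, 8, 8))
  rep2 <- overlap_report(s1, s2_fine)
  expect_true(rep2$resampled)
  expect_gt(rep2$dice, 0.95)
})
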