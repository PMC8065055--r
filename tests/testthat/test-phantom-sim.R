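test_that("multi-cone layouts are deterministic and well-conditioned", {
  c7 <- make_multicone(7)
  expect_equal(length(c7), 7L)
  expect_identical(c7$frame, "CAD")
  # non-coplanar: third singular value of the centred cloud is substantial
  sv <- svd(scale(c7$points, scale = FALSE))$d
  expect_gt(sv[3] / sv[1], 0.01)

  c18 <- make_multicone(18, extent = c(120, 160))
  expect_equal(length(c18), 18L)
  expect_identical(make_multicone(7), make_multicone(7))      # bitwise
  j1 <- make_multicone(7, height_jitter_mm = 1, seed = 4)
  expect_identical(j1, make_multicone(7, height_jitter_mm = 1, seed = 4))
  expect_false(identical(j1$points, c7$points))
  expect_error(make_multicone(2), "at least 3")
})

test_that("rendered phantoms honour the gland geometry and mask oracles", {
  spec <- phantom_spec()
  # default gland semi-axes span the 4 x 4.5 x 4 cm bounding box
  expect_equal(2 * spec$gland_semiaxes, c(40, 45, 40))
  expect_equal(spec$lesion_radius_mm, 5)
  expect_equal(nrow(spec$lesion_centers), 3L)
  expect_error(phantom_spec(lesion_centers = rbind(c(19, 0, 0))),
               "inside the gland")

  ph <- render_phantom(spec, "mr", spacing = 0.5, seed = NULL)
  vol_mm3 <- vapply(ph$lesion_masks, function(m) {
    sum(m$voxels) * prod(m$spacing)
  }, 0)
  expect_true(all(abs(vol_mm3 - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3)
                  < 0.02))
  # centroid of each rendered lesion is at its analytic centre
  for (k in 1:3) {
    ctr <- colMeans(voxel_to_world(
      ph$lesion_masks[[k]],
      which(ph$lesion_masks[[k]]$voxels > 0.5, arr.ind = TRUE) - 1L))
    expect_lt(max(abs(ctr - spec$lesion_centers[k, ])), 0.25 * 0.5)
  }
  expect_identical(render_phantom(spec, "mr", spacing = 1, seed = 8)$image,
                   render_phantom(spec, "mr", spacing = 1, seed = 8)$image)
  expect_error(render_phantom(spec, "mr", spacing = 3), "resolve")
  # US mode applies depth attenuation: mean gland intensity drops with z
  us <- render_phantom(spec, "us", spacing = 1, seed = 2)
  expect_true(all(us$image$voxels >= 0))
})

test_that("simulated tracker jitter matches its sampling oracle", {
  pose <- random_rigid(81, "tool", "tracker")
  s0 <- simulate_tracker(pose, 20, sigma_mm = 0, sigma_rot_deg = 0, seed = 1)
  for (i in c(1, 10, 20)) {
    expect_lt(max(abs(pose_at(s0, i)$matrix - pose$matrix)), 1e-9)
  }
  s <- simulate_tracker(pose, 10000, sigma_mm = 0.3, sigma_rot_deg = 0.05,
                        seed = 2)
  jitter <- sqrt(rowSums(sweep(cbind(s$tx, s$ty, s$tz), 2,
                               pose$matrix[1:3, 4])^2))
  expect_equal(sqrt(mean(jitter^2)), 0.3 * sqrt(3), tolerance = 0.02)
  expect_identical(simulate_tracker(pose, 50, 0.3, seed = 9),
                   simulate_tracker(pose, 50, 0.3, seed = 9))
})

test_that("zero-noise experiments reproduce ground truth end to end", {
  truth <- experiment_truth(noise_scale = 0)
  b <- simulate_experiment(truth, seed = 101)
  f <- fuse_experiment(b)
  expect_lt(f$tre_lesions$mean_mm, 1e-6)
  expect_lt(f$tre_cones$mean_mm, 1e-6)
  expect_lt(f$tre_trus$mean_mm, 1e-6)

  # with no physical table motion, shift-compensated and plain chains agree
  truth0 <- experiment_truth(noise_scale = 0, table_shift_mm = c(0, 0, 0))
  b0 <- simulate_experiment(truth0, seed = 102)
  f_shift <- fuse_experiment(b0, use_table_shift = TRUE)
  f_plain <- fuse_experiment(b0, use_table_shift = FALSE)
  expect_lt(max(abs(f_shift$t_us_mr$matrix - f_plain$t_us_mr$matrix)), 1e-9)
})

test_that("noisy experiment bundles are reproducible under the master seed", {
  truth <- experiment_truth()
  b1 <- simulate_experiment(truth, seed = 202)
  b2 <- simulate_experiment(truth, seed = 202)
  expect_identical(b1$us_cal_observations[[1]]$image_tips$points,
                   b2$us_cal_observations[[1]]$image_tips$points)
  expect_identical(b1$mr_cal$tips_in_reference$repeats,
                   b2$mr_cal$tips_in_reference$repeats)
  b3 <- simulate_experiment(truth, seed = 203)
  expect_false(identical(b1$us_cal_observations[[1]]$image_tips$points,
                         b3$us_cal_observations[[1]]$image_tips$points))
})

test_that("US pair simulation carries exact ground truth for registration", {
  pair <- simulate_us_pair(5, spacing = 2)
  expect_s3_class(pair$t_true, "frame_transform")
  expect_false(pair$t_true$rigid)
  expect_identical(pair$fixed$frame, "US")
  # mapping moving lesion positions through the truth lands on fixed ones
  les_moving <- apply_transform(invert(pair$t_true), pair$lesion_centers)
  back <- apply_transform(pair$t_true, les_moving)
  expect_lt(max(abs(back - pair$lesion_centers)), 1e-9)
  expect_identical(simulate_us_pair(5, spacing = 2)$moving$voxels,
                   pair$moving$voxels)
})
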