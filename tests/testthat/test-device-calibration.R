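# Build a synthetic pivot sweep: tool rotates about a fixed tip location.
make_pivot_stream <- function(n, tip_tool, pivot_world, sigma = 0,
                              seed = 1, span = 1.2) {
  set.seed(seed)
  trans <- matrix(0, n, 3)
  quat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    R <- rotation_matrix(rnorm(3), runif(1, -span, span))
    t <- pivot_world - R %*% tip_tool + rnorm(3, sd = sigma)
    trans[i, ] <- t
    quat[i, ] <- matrix_to_quaternion(R)
  }
  pose_stream(seq_len(n) * 0.1, rep("stylus", n), trans, quat)
}

test_that("pivot calibration recovers the stylus tip", {
  tip <- c(1.5, -2, 120)
  pivot <- c(40, 60, -800)
  s <- make_pivot_stream(50, tip, pivot, sigma = 0, seed = 2)
  cal <- calibrate_pivot(s)
  expect_lt(max(abs(cal$tip_tool - tip)), 1e-9)
  expect_lt(max(abs(cal$pivot_tracker - pivot)), 1e-9)
  expect_lt(cal$residual_rms_mm, 1e-9)

  sn <- make_pivot_stream(1000, tip, pivot, sigma = 0.2, seed = 3)
  caln <- calibrate_pivot(sn)
  expect_equal(caln$residual_rms_mm, 0.2 * sqrt(3), tolerance = 0.2)
  expect_lt(max(abs(caln$tip_tool - tip)), 0.1)

  # pure translation: no orientation variation -> degenerate
  n <- 20
  flat <- pose_stream(seq_len(n), rep("stylus", n),
                      cbind(seq_len(n), 0, 0),
                      matrix(rep(c(0, 0, 0, 1), n), n, 4, byrow = TRUE))
  expect_error(calibrate_pivot(flat), "degenerate")
  expect_error(calibrate_pivot(make_pivot_stream(5, tip, pivot)),
               "at least 10")
})

test_that("US probe calibration recovers T_US^trans and pools observations", {
  truth <- experiment_truth(noise_scale = 0)
  b <- simulate_experiment(truth, seed = 1)
  cal <- calibrate_us_probe(b$us_cal_observations)
  expect_lt(cal$fre_mm, 1e-9)
  expect_lt(max(abs(cal$image_to_tool$matrix -
                    truth$transforms$t_us_trans$matrix)), 1e-8)
  expect_identical(cal$image_to_tool$source, "US")
  expect_identical(cal$image_to_tool$target, "trans")

  # single observation is already exact in the noiseless world
  cal1 <- calibrate_us_probe(b$us_cal_observations[1])
  expect_lt(cal1$fre_mm, 1e-9)

  # frame mismatch in a pose is a chain error
  bad <- b$us_cal_observations
  bad[[1]]$pose_tank$source <- "elsewhere"
  expect_error(calibrate_us_probe(bad), "does not match")
})

test_that("probe calibration error shrinks with more observations", {
  truth <- experiment_truth()   # default noise
  err_for <- function(n_obs, reps = 25) {
    errs <- numeric(reps)
    for (r in seq_len(reps)) {
      b <- simulate_experiment(truth, seed = 1000 + r)
      cal <- calibrate_us_probe(b$us_cal_observations[seq_len(n_obs)])
      delta <- compose(invert(truth$transforms$t_us_trans),
                       cal$image_to_tool)
      errs[r] <- sqrt(sum(delta$matrix[1:3, 4]^2))
    }
    mean(errs)
  }
  e1 <- err_for(1)
  e5 <- err_for(5)
  expect_lt(e5, e1)
})

test_that("probe calibration is invariant to a global tracker motion", {
  truth <- experiment_truth()
  b <- simulate_experiment(truth, seed = 77)
  cal <- calibrate_us_probe(b$us_cal_observations)
  g <- random_rigid(9, "tracker", "tracker")
  moved <- lapply(b$us_cal_observations, function(ob) {
    ob$pose_probe <- compose(g, ob$pose_probe)
    ob$pose_tank <- compose(g, ob$pose_tank)
    ob
  })
  cal2 <- calibrate_us_probe(moved)
  expect_lt(max(abs(cal$image_to_tool$matrix - cal2$image_to_tool$matrix)),
            1e-9)
})

test_that("TRUS calibration lifts in-plane points and handles coplanarity", {
  t_true <- random_rigid(13, "TRUS", "trus_tool", max_angle = 1)
  pose_probe <- random_rigid(14, "trus_tool", "tracker")
  set.seed(15)
  px <- cbind(runif(15, 0, 400), runif(15, 0, 300))
  spacing <- c(0.15, 0.15)
  img_mm <- cbind(px[, 1] * spacing[1], px[, 2] * spacing[2], 0)
  tips_tracker <- apply_transform(pose_probe,
                                  apply_transform(t_true, img_mm))
  cal <- calibrate_trus_probe(px, spacing, tips_tracker, pose_probe)
  expect_lt(cal$fre_mm, 1e-9)
  expect_true(cal$registration$coplanar)
  expect_lt(max(abs(cal$image_to_tool$matrix - t_true$matrix)), 1e-8)

  # noisy pointer tips: FRE close to the coplanar-N Fitzpatrick level
  set.seed(16)
  fle <- 0.3                    # 3D RMS of the pointer-tip noise
  fre <- replicate(400, {
    noisy <- tips_tracker + matrix(rnorm(45, sd = fle / sqrt(3)), 15, 3)
    calibrate_trus_probe(px, spacing, noisy, pose_probe)$fre_mm
  })
  expect_equal(sqrt(mean(fre^2)), sqrt((1 - 2 / 15)) * fle, tolerance = 0.1)

  coll <- cbind(1:5, 2 * (1:5))
  tips_coll <- apply_transform(pose_probe, apply_transform(
    t_true, cbind(coll[, 1] * spacing[1], coll[, 2] * spacing[2], 0)))
  expect_error(calibrate_trus_probe(coll, spacing, tips_coll, pose_probe),
               "collinear")
})

test_that("MR calibration averages repeats and benefits from them", {
  truth <- experiment_truth(noise_scale = 0)
  b <- simulate_experiment(truth, seed = 5)
  cal <- calibrate_mr(b$mr_cal$tips_in_reference, b$mr_cal$tips_in_mr)
  expect_lt(cal$fre_mm, 1e-9)
  expect_lt(max(abs(cal$mr_to_reference$matrix -
                    truth$transforms$t_mr_table$matrix)), 1e-8)
  expect_identical(cal$reference_frame, "ORF_TABLE")

  tips2 <- subset_fiducials(b$mr_cal$tips_in_mr,
                            b$mr_cal$tips_in_mr$labels[1:2])
  expect_error(calibrate_mr(tips2, tips2), "at least 3")

  # 5 repeats/tip beat a single reading (Monte-Carlo)
  mr_tips <- make_multicone(18, extent = c(120, 160), frame = "MR")
  t_true <- random_rigid(23, "MR", "ORF_TABLE")
  tips_tab <- apply_transform(t_true, mr_tips)
  set.seed(24)
  fre_avg <- fre_one <- numeric(100)
  for (r in 1:100) {
    reps <- lapply(tips_tab$labels, function(lab) {
      sweep(matrix(rnorm(15, sd = 0.3), 5, 3), 2, tips_tab$points[lab, ], `+`)
    })
    names(reps) <- tips_tab$labels
    with_reps <- fiducial_set(t(vapply(reps, function(r) r[1, ],
                                       numeric(3))),
                              "ORF_TABLE", tips_tab$labels, repeats = reps)
    fre_avg[r] <- calibrate_mr(with_reps, mr_tips)$fre_mm
    one <- fiducial_set(with_reps$points, "ORF_TABLE", tips_tab$labels)
    fre_one[r] <- calibrate_mr(one, mr_tips)$fre_mm
  }
  expect_lt(mean(fre_avg), mean(fre_one))
})

test_that("table shift tracking recovers the inter-epoch motion", {
  pose <- random_rigid(31, "ORF_TABLE", "tracker")
  before <- simulate_tracker(pose, 50, sigma_mm = 0, sigma_rot_deg = 0,
                             seed = 1)
  shift0 <- track_table_shift(before, before, "ORF_TABLE")
  expect_lt(max(abs(shift0$matrix - diag(4))), 1e-12)
  expect_identical(shift0$source, "ORF_moved")
  expect_identical(shift0$target, "ORF_TABLE")

  moved <- compose(transform_translation(c(0, 200, 0), "tracker", "tracker"),
                   pose)
  after <- simulate_tracker(moved, 50, 0, 0, seed = 2)
  shift <- track_table_shift(before, after, "ORF_TABLE")
  # pure world translation: no rotation, 200 mm magnitude
  expect_lt(max(abs(shift$matrix[1:3, 1:3] - diag(3))), 1e-9)
  expect_equal(sqrt(sum(shift$matrix[1:3, 4]^2)), 200, tolerance = 1e-9)

  before_j <- simulate_tracker(pose, 100, 0.3, 0.05, seed = 3)
  after_j <- simulate_tracker(moved, 100, 0.3, 0.05, seed = 4)
  shift_j <- track_table_shift(before_j, after_j, "ORF_TABLE")
  expect_lt(max(abs(shift_j$matrix[1:3, 4] - shift$matrix[1:3, 4])), 0.3)

  empty <- before[before$tool_id == "nope", ]
  class(empty) <- class(before)
  attr(empty, "tracker_frame") <- "tracker"
  expect_error(track_table_shift(empty, after, "ORF_TABLE"),
               "no valid readings")
})

test_that("calibration FRE is non-increasing in stylus repeats", {
  mr_tips <- make_multicone(18, extent = c(120, 160), frame = "MR")
  t_true <- random_rigid(51, "MR", "ORF_TABLE")
  tips_tab <- apply_transform(t_true, mr_tips)
  fre_k <- vapply(c(1, 3, 10), function(k) {
    set.seed(300)   # fixed seed grid across k
    mean(replicate(40, {
      reps <- lapply(tips_tab$labels, function(lab) {
        sweep(matrix(rnorm(3 * k, sd = 0.3), k, 3), 2,
              tips_tab$points[lab, ], `+`)
      })
      names(reps) <- tips_tab$labels
      fs <- fiducial_set(t(vapply(reps, function(r) r[1, ], numeric(3))),
                         "ORF_TABLE", tips_tab$labels, repeats = reps)
      calibrate_mr(fs, mr_tips)$fre_mm
    }))
  }, 0)
  expect_true(all(diff(fre_k) < 0))
})
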