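test_that("register_points recovers exact rigid motions and reports FRE", {
  fixed <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                              c(0, 0, 10)), "tank")
  reg0 <- register_points(fixed, fixed)
  expect_equal(reg0$fre_mm, 0)
  expect_lt(max(abs(reg0$transform$matrix - diag(4))), 1e-12)

  truth <- compose(transform_translation(c(1, 2, 3), "tank", "tank"),
                   transform_rotation("z", pi / 2, "tank", "tank"))
  axis_pts <- fiducial_set(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                 c(0, 0, 0)), "US")
  moved <- fiducial_set(apply_transform(
    rigid_transform(truth$matrix, "US", "tank"), axis_pts$points),
    "tank", axis_pts$labels)
  reg <- register_points(axis_pts, moved)
  expect_lt(reg$fre_mm, 1e-10)
  expect_lt(max(abs(reg$transform$matrix - truth$matrix)), 1e-10)
  # result independent of point ordering given label pairing
  shuffled <- subset_fiducials(axis_pts, rev(axis_pts$labels))
  expect_lt(max(abs(register_points(shuffled, moved)$transform$matrix -
                    reg$transform$matrix)), 1e-10)

  # degeneracies
  line <- fiducial_set(cbind(1:4, 0, 0), "A")
  line_f <- fiducial_set(cbind(1:4, 0, 1), "B", line$labels)
  expect_error(register_points(line, line_f), "collinear")
  expect_error(register_points(subset_fiducials(fixed, fixed$labels[1:2]),
                               subset_fiducials(fixed, fixed$labels[1:2])),
               "at least 3")
})

test_that("coplanar sets are solved with a proper rotation and flagged", {
  sq <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                           c(10, 10, 0), c(5, 2, 0)), "TRUS")
  t <- random_rigid(5, "TRUS", "trans", max_angle = 1)
  moved <- fiducial_set(apply_transform(t, sq$points), "trans", sq$labels)
  reg <- register_points(sq, moved)
  expect_true(reg$coplanar)
  expect_equal(det(reg$transform$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
  expect_lt(reg$fre_mm, 1e-9)
})

test_that("FRE is equivariant and optimal among rigid transforms", {
  set.seed(42)
  m <- random_fiducials(1, n = 7, frame = "US")
  f <- fiducial_set(apply_transform(random_rigid(2, "US", "tank"), m$points) +
                      matrix(rnorm(21, sd = 0.3), 7, 3), "tank", m$labels)
  reg <- register_points(m, f)

  # pre-rotating both sets by the same motion leaves FRE unchanged
  g <- random_rigid(3, "tank", "tank")
  m2 <- fiducial_set(apply_transform(
    rigid_transform(g$matrix, "US", "US"), m$points), "US", m$labels)
  f2 <- fiducial_set(apply_transform(g, f$points), "tank", f$labels)
  expect_equal(register_points(m2, f2)$fre_mm, reg$fre_mm,
               tolerance = 1e-9)

  # optimality: perturbing the solution never lowers the residual
  fre_of <- function(tr) {
    sqrt(mean(rowSums((apply_transform(tr, m$points) - f$points)^2)))
  }
  for (s in 1:10) {
    pert <- compose(random_rigid(100 + s, "tank", "tank",
                                 max_angle = 0.05, max_trans = 0.5),
                    reg$transform)
    expect_gte(fre_of(pert), reg$fre_mm - 1e-12)
  }
  expect_equal(reg$fre_mm, sqrt(mean(reg$per_point_residuals_mm^2)),
               tolerance = 1e-12)
})

test_that("mean squared FRE follows the (1 - 2/N) expectation", {
  # isotropic FLE with 3D RMS 0.3 mm => per-axis SD 0.3/sqrt(3); quick
  # check at 2000 replicates (acceptance re-runs at 10^4, 5%)
  set.seed(7)
  tips <- make_multicone(7, frame = "tank")$points
  sd_axis <- 0.3 / sqrt(3)
  fre2 <- replicate(2000, {
    noisy <- fiducial_set(tips + matrix(rnorm(21, sd = sd_axis), 7, 3),
                          "US", rownames(tips))
    register_points(noisy, fiducial_set(tips, "tank", rownames(tips)))$fre_mm^2
  })
  expect_equal(mean(fre2), (1 - 2 / 7) * 0.3^2, tolerance = 0.1)
})

test_that("TRE at held-out targets exceeds FRE and vanishes with noise", {
  id <- transform_identity("tank")
  targets <- random_fiducials(11, n = 5, frame = "tank")
  tre0 <- compute_tre(targets, targets, id)
  expect_equal(unname(tre0$per_target_mm), rep(0, 5))

  one <- fiducial_set(rbind(c(0, 0, 0)), "tank", "t1")
  moved <- fiducial_set(rbind(c(1, 0, 0)), "tank", "t1")
  expect_equal(compute_tre(one, moved, id)$mean_mm, 1.0)
  expect_error(compute_tre(one, fiducial_set(rbind(c(1, 0, 0)), "tank", "x"),
                           id), "unpaired")

  # US-calibration replica: 7 calibration tips, 70 held-out targets
  set.seed(12)
  tips <- make_multicone(7, frame = "tank")$points
  tgt <- matrix(runif(210, -60, 60), 70, 3)
  run_once <- function(sd_axis) {
    cal_m <- fiducial_set(tips + matrix(rnorm(21, sd = sd_axis), 7, 3), "US",
                          rownames(tips))
    reg <- register_points(cal_m, fiducial_set(tips, "tank", rownames(tips)))
    tgt_m <- fiducial_set(tgt + matrix(rnorm(210, sd = sd_axis), 70, 3), "US")
    c(fre = reg$fre_mm,
      tre = compute_tre(tgt_m, fiducial_set(tgt, "tank", tgt_m$labels),
                        reg$transform)$mean_mm)
  }
  res <- replicate(100, run_once(0.3 / sqrt(3)))
  expect_gt(mean(res["tre", ]), mean(res["fre", ]))
  res0 <- replicate(5, run_once(1e-4 / sqrt(3)))
  expect_lt(mean(res0["tre", ]), 1e-3)
})

test_that("CAD refinement reduces fiducial noise", {
  cad <- make_multicone(7, frame = "CAD")
  t_true <- random_rigid(21, "CAD", "tank")
  truth_tank <- apply_transform(t_true, cad)

  # already-aligned and noiseless cases are exact
  aligned <- refine_fiducials_via_cad(
    fiducial_set(cad$points, "tank", cad$labels), cad)
  expect_lt(max(abs(aligned$points - cad$points)), 1e-10)
  expect_equal(attr(aligned, "cad_fit_fre_mm"), 0, tolerance = 1e-10)
  noiseless <- refine_fiducials_via_cad(truth_tank, cad)
  expect_lt(max(abs(noiseless$points - truth_tank$points)), 1e-10)

  # variance reduction under noise (Monte-Carlo)
  set.seed(31)
  raw_err <- ref_err <- numeric(200)
  for (r in 1:200) {
    measured <- fiducial_set(truth_tank$points +
                               matrix(rnorm(21, sd = 0.3), 7, 3),
                             "tank", cad$labels)
    refined <- refine_fiducials_via_cad(measured, cad)
    raw_err[r] <- sqrt(mean((measured$points - truth_tank$points)^2))
    ref_err[r] <- sqrt(mean((refined$points - truth_tank$points)^2))
  }
  expect_lt(mean(ref_err), mean(raw_err))
})

test_that("average_repeats averages, rejects outliers and estimates jitter", {
  # single reading: unchanged, zero spread
  fs <- random_fiducials(41, n = 3)
  av <- average_repeats(fs)
  expect_equal(av$points, fs$points)
  expect_equal(unname(attr(av, "spread_mm")), rep(0, 3))

  # two-reading arithmetic: mean (1,0,0), spread 1 mm
  two <- fiducial_set(rbind(c(0, 0, 0)), "tank", "a",
                      repeats = list(a = rbind(c(0, 0, 0), c(2, 0, 0))))
  av2 <- average_repeats(two)
  expect_equal(unname(av2$points["a", ]), c(1, 0, 0))
  expect_equal(unname(attr(av2, "spread_mm")["a"]), 1.0)

  # a gross outlier is rejected, the mean stays near truth
  out <- fiducial_set(rbind(c(0, 0, 0)), "tank", "a",
                      repeats = list(a = rbind(matrix(rnorm(27, sd = 0.1),
                                                      9, 3),
                                               c(50, 0, 0))))
  avo <- average_repeats(out)
  expect_equal(unname(attr(avo, "n_rejected")["a"]), 1L)
  expect_lt(sqrt(sum(avo$points["a", ]^2)), 1)

  expect_error(
    fiducial_set(rbind(c(0, 0, 0)), "tank", "a",
                 repeats = list(a = matrix(0, 0, 3))),
    "non-empty")

  # sampling-theory oracle: pooled RMS spread ~ sigma*sqrt(3)*sqrt(9/10)
  set.seed(55)
  n_lab <- 2000
  truthp <- matrix(rnorm(n_lab * 3, sd = 40), n_lab, 3)
  reps <- lapply(seq_len(n_lab), function(i) {
    sweep(matrix(rnorm(30, sd = 0.3), 10, 3), 2, truthp[i, ], `+`)
  })
  names(reps) <- paste0("F", seq_len(n_lab))
  big <- fiducial_set(truthp, "tank", names(reps), repeats = reps)
  avb <- average_repeats(big)
  pooled_rms <- sqrt(mean(attr(avb, "spread_mm")^2))
  expect_equal(pooled_rms, 0.3 * sqrt(3) * sqrt(9 / 10), tolerance = 0.02)
})
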