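#' Multi-cone calibration phantom tip layouts
#'
#' Deterministic labelled cone-tip coordinates for the two calibration
#' phantoms: a 7-cone layout used for the 3D-US probe calibration and an
#' 18-cone layout used for the MR calibration. Tips are arranged on a grid
#' across the base plate with systematically varied cone heights, so the
#' configuration is well-conditioned (non-coplanar) for rigid
#' registration.
#'
#' @param n Number of cones (>= 3; presets 7 and 18).
#' @param extent Base-plate extent `c(width, depth)` in mm (default
#'   `c(100, 100)`).
#' @param heights Optional length-`n` cone heights in mm; default a
#'   deterministic spread over 15-40 mm.
#' @param frame Frame name (default `"CAD"`).
#' @param height_jitter_mm Optional SD of height perturbations (with
#'   `seed`), 0 by default.
#' @param seed Seed for the optional jitter.
#' @return A `fiducial_set` of `n` labelled tips.
#' @export
make_multicone <- function(n = 7L, extent = c(100, 100), heights = NULL,
                           frame = "CAD", height_jitter_mm = 0,
                           seed = NULL) {
  n <- as.integer(n)
  if (n < 3L) stop("a multi-cone phantom needs at least 3 cones")
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  xs <- if (ncol_grid == 1L) 0 else
    seq(-extent[1] / 2, extent[1] / 2, length.out = ncol_grid)
  ys <- if (nrow_grid == 1L) 0 else
    seq(-extent[2] / 2, extent[2] / 2, length.out = nrow_grid)
  grid <- expand.grid(x = xs, y = ys)[seq_len(n), ]
  if (is.null(heights)) {
    # low-discrepancy spread of heights over 15-40 mm (golden-ratio walk)
    heights <- 15 + 25 * (((seq_len(n) - 1L) * 0.6180339887498949) %% 1)
  }
  stopifnot(length(heights) == n)
  if (height_jitter_mm > 0) {
    heights <- heights +
      .with_seed(seed, rnorm(n, sd = height_jitter_mm))
  }
  fiducial_set(cbind(grid$x, grid$y, heights), frame,
               labels = sprintf("cone%02d", seq_len(n)))
}

#' Prostate phantom specification
#'
#' Geometry and per-modality appearance of the tissue-equivalent prostate
#' phantom: an ellipsoidal gland (default semi-axes 20 x 22.5 x 20 mm,
#' i.e. a 4 x 4.5 x 4 cm bounding box) containing spherical lesions of
#' 5 mm radius (the smallest clinically significant tumour size), in a
#' low-scatter background.
#'
#' @param gland_semiaxes Length-3 semi-axes in mm.
#' @param gland_center Length-3 gland centre in mm.
#' @param lesion_centers N x 3 matrix of lesion centres in mm (default
#'   three non-collinear lesions inside the gland).
#' @param lesion_radius_mm Lesion radius in mm (default 5).
#' @param appearance Named list of per-modality intensity parameters; see
#'   Details.
#' @details The default appearance is `mr = list(background = 10, gland =
#' 60, lesion = 100, noise_sd = 3)` (piecewise-constant plus additive
#' Gaussian noise) and `us = list(background = 5, gland = 40, lesion = 70,
#' speckle_shape = 16, attenuation_per_mm = 0.008)` (multiplicative gamma
#' speckle and exponential depth attenuation along +z). This is an
#' appearance model sufficient to exercise intensity-based registration,
#' not an acoustic simulator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(gland_semiaxes = c(20, 22.5, 20),
                         gland_center = c(0, 0, 0),
                         lesion_centers = NULL,
                         lesion_radius_mm = 5,
                         appearance = NULL) {
  if (is.null(lesion_centers)) {
    lesion_centers <- rbind(c(-8, 6, -5), c(9, -4, 2), c(-2, -9, 8))
    lesion_centers <- sweep(lesion_centers, 2L, gland_center, `+`)
  }
  lesion_centers <- as.matrix(lesion_centers)
  stopifnot(ncol(lesion_centers) == 3L, lesion_radius_mm > 0,
            length(gland_semiaxes) == 3L, all(gland_semiaxes > 0))
  # lesions (including their full radius) must sit inside the gland
  u <- sweep(lesion_centers, 2L, gland_center)
  margin <- 1 - lesion_radius_mm / min(gland_semiaxes)
  radial <- sqrt((u[, 1] / gland_semiaxes[1])^2 +
                 (u[, 2] / gland_semiaxes[2])^2 +
                 (u[, 3] / gland_semiaxes[3])^2)
  if (any(radial > margin)) {
    stop("lesions must lie fully inside the gland ellipsoid")
  }
  app <- list(
    mr = list(background = 10, gland = 60, lesion = 100, noise_sd = 3),
    us = list(background = 5, gland = 40, lesion = 70, speckle_shape = 16,
              attenuation_per_mm = 0.008))
  if (!is.null(appearance)) {
    for (m in names(appearance)) {
      app[[m]][names(appearance[[m]])] <- appearance[[m]]
    }
  }
  structure(list(gland_semiaxes = gland_semiaxes,
                 gland_center = gland_center,
                 lesion_centers = lesion_centers,
                 lesion_radius_mm = lesion_radius_mm,
                 appearance = app),
            class = "phantom_spec")
}

#' Render a prostate phantom volume
#'
#' Rasterizes the phantom onto a regular grid with partial-volume edges
#' (intensity ramps over one voxel at structure boundaries) and the
#' modality-specific appearance of [phantom_spec()]. Lesion and gland
#' masks are exact by construction (voxel centres inside the analytic
#' surface).
#'
#' @param spec A `phantom_spec`.
#' @param modality `"mr"` or `"us"`.
#' @param spacing Isotropic voxel size in mm (default 1); must resolve the
#'   smallest lesion with at least 4 voxels across.
#' @param margin_mm Padding around the gland bounding box (default 12).
#' @param frame Frame name of the volume (default `"MR"` or `"US"` per
#'   modality).
#' @param seed Seed for the noise/speckle draw (`NULL` = noiseless).
#' @return List with `image` (`volume_image`), `gland_mask`
#'   (`label_mask`), `lesion_masks` (named list of `label_mask`s) and
#'   `spec`.
#' @export
render_phantom <- function(spec, modality = c("mr", "us"), spacing = 1,
                           margin_mm = 12, frame = NULL, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  modality <- match.arg(modality)
  if (is.null(frame)) frame <- toupper(modality)
  if (2 * spec$lesion_radius_mm / spacing < 4) {
    stop("grid spacing ", spacing,
         " mm does not resolve the smallest lesion with >= 4 voxels")
  }
  lo <- spec$gland_center - spec$gland_semiaxes - margin_mm
  hi <- spec$gland_center + spec$gland_semiaxes + margin_mm
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  origin <- lo
  grid <- volume_image(array(0, dims), spacing = rep(spacing, 3L),
                       origin = origin, frame = frame)
  ctr <- voxel_centers(grid)
  if (any(sweep(spec$lesion_centers, 2L, lo, `-`) < 0) ||
      any(sweep(spec$lesion_centers, 2L, hi, `-`) > 0)) {
    stop("lesion outside the rendered grid")
  }

  # partial-volume weight: 1 inside, 0 outside, linear ramp over one voxel
  pv <- function(signed_dist) pmin(1, pmax(0, 0.5 - signed_dist / spacing))

  u <- sweep(ctr, 2L, spec$gland_center)
  radial <- sqrt((u[, 1] / spec$gland_semiaxes[1])^2 +
                 (u[, 2] / spec$gland_semiaxes[2])^2 +
                 (u[, 3] / spec$gland_semiaxes[3])^2)
  # approximate signed distance to the ellipsoid surface
  gland_sd <- (radial - 1) * min(spec$gland_semiaxes)
  gland_w <- pv(gland_sd)

  n_les <- nrow(spec$lesion_centers)
  lesion_w <- matrix(0, nrow(ctr), n_les)
  lesion_in <- matrix(FALSE, nrow(ctr), n_les)
  for (k in seq_len(n_les)) {
    d <- sqrt(rowSums(sweep(ctr, 2L, spec$lesion_centers[k, ])^2))
    lesion_w[, k] <- pv(d - spec$lesion_radius_mm)
    lesion_in[, k] <- d <= spec$lesion_radius_mm
  }
  les_w <- 0
  for (k in seq_len(n_les)) les_w <- pmax(les_w, lesion_w[, k])

  ap <- spec$appearance[[modality]]
  base <- ap$background +
    (ap$gland - ap$background) * gland_w +
    (ap$lesion - ap$gland) * les_w
  vox <- if (modality == "mr") {
    noise <- if (is.null(seed)) 0 else
      .with_seed(seed, rnorm(length(base), sd = ap$noise_sd))
    base + noise
  } else {
    depth <- ctr[, 3] - lo[3]
    att <- exp(-ap$attenuation_per_mm * depth)
    speckle <- if (is.null(seed)) 1 else
      .with_seed(seed, rgamma(length(base), shape = ap$speckle_shape,
                              rate = ap$speckle_shape))
    base * att * speckle
  }
  image <- volume_image(array(vox, dims), rep(spacing, 3L), origin,
                        frame = frame)
  gland_mask <- label_mask(array(radial <= 1, dims), rep(spacing, 3L),
                           origin, frame = frame)
  lesion_masks <- lapply(seq_len(n_les), function(k) {
    label_mask(array(lesion_in[, k], dims), rep(spacing, 3L), origin,
               frame = frame)
  })
  names(lesion_masks) <- sprintf("lesion%d", seq_len(n_les))
  list(image = image, gland_mask = gland_mask, lesion_masks = lesion_masks,
       spec = spec)
}

#' Simulate jittered tracker readings of a static pose
#'
#' Emulates an optical tracker observing a statically held tool: each
#' reading is the true pose perturbed by isotropic translational jitter
#' (per-axis SD `sigma_mm`, so the RMS 3D jitter magnitude is
#' `sigma_mm * sqrt(3)`) and a small random rotation (axis-angle with
#' per-axis SD `sigma_rot_deg`).
#'
#' @param pose True rigid `frame_transform` tool -> tracker.
#' @param n_readings Number of readings.
#' @param sigma_mm Translational jitter per axis (mm).
#' @param sigma_rot_deg Rotational jitter per axis (degrees, default
#'   0.05).
#' @param t0,dt Start time and sampling interval (s).
#' @param seed Seed (`NULL` = leave RNG state alone).
#' @return A `pose_stream` of the tool.
#' @export
simulate_tracker <- function(pose, n_readings, sigma_mm,
                             sigma_rot_deg = 0.05, t0 = 0, dt = 0.1,
                             seed = NULL) {
  stopifnot(is_frame_transform(pose), pose$rigid, n_readings >= 1L,
            sigma_mm >= 0, sigma_rot_deg >= 0)
  gen <- function() {
    R0 <- pose$matrix[1:3, 1:3]
    tr0 <- pose$matrix[1:3, 4]
    trans <- matrix(rnorm(3L * n_readings, sd = sigma_mm), n_readings, 3L)
    trans <- sweep(trans, 2L, tr0, `+`)
    quat <- matrix(0, n_readings, 4L)
    sig_rad <- sigma_rot_deg * pi / 180
    for (i in seq_len(n_readings)) {
      Ri <- R0
      if (sig_rad > 0) {
        w <- rnorm(3L, sd = sig_rad)
        ang <- sqrt(sum(w^2))
        if (ang > 0) Ri <- rotation_matrix(w, ang) %*% R0
      }
      quat[i, ] <- matrix_to_quaternion(Ri)
    }
    pose_stream(t0 + dt * (seq_len(n_readings) - 1L),
                rep(pose$source, n_readings), trans, quat,
                tracker_frame = pose$target)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

# Perturb fiducial points by isotropic Gaussian localization noise
# (per-axis SD sigma_mm).
.perturb_points <- function(fs, sigma_mm) {
  if (sigma_mm <= 0) return(fs)
  fs$points <- fs$points +
    matrix(rnorm(length(fs$points), sd = sigma_mm), nrow(fs$points), 3L)
  fs
}

# Repeated noisy readings of each fiducial.
.make_repeats <- function(fs, n_repeats, sigma_mm) {
  reps <- lapply(fs$labels, function(lab) {
    sweep(matrix(rnorm(3L * n_repeats, sd = sigma_mm), n_repeats, 3L),
          2L, fs$points[lab, ], `+`)
  })
  names(reps) <- fs$labels
  first <- t(vapply(reps, function(r) r[1L, ], numeric(3L)))
  fiducial_set(first, fs$frame, fs$labels, repeats = reps)
}

#' Simulate an intra-modal US/US registration test pair
#'
#' Builds the standard test case for the intra-modal registration step: the
#' prostate phantom rendered twice with US appearance and independent
#' speckle realizations, the moving volume resampled through a known
#' gland-centred affine (rotation, translation, anisotropic scale drawn
#' uniformly within the given bounds), plus ellipsoidal gland ROI masks for
#' both volumes. Recovering the affine and mapping the lesion centroids
#' quantifies the registration error against exact ground truth.
#'
#' @param seed Seed controlling the drawn motion and both speckle draws.
#' @param max_rot_deg,max_trans_mm Bounds of the drawn rotation (single
#'   axis-angle, degrees) and per-axis translation (mm); defaults 10 / 5.
#' @param max_scale Bound of the per-axis relative scale deviation
#'   (default 0.03).
#' @param spacing Rendered voxel size in mm (default 1.5).
#' @param spec A [phantom_spec()] (default standard phantom).
#' @return List with `fixed`, `moving` (`volume_image`s, both frame
#'   `"US"`), `fixed_mask`, `moving_mask` (`label_mask`s), `t_true`
#'   (affine moving -> fixed), and `lesion_centers` (fixed frame, mm).
#' @export
simulate_us_pair <- function(seed, max_rot_deg = 10, max_trans_mm = 5,
                             max_scale = 0.03, spacing = 1.5,
                             spec = phantom_spec()) {
  base <- render_phantom(spec, "us", spacing = spacing, frame = "US",
                         seed = NULL)
  P <- base$image
  .with_seed(seed, {
    ang <- runif(1, -max_rot_deg, max_rot_deg) * pi / 180
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    sc <- 1 + runif(3, -max_scale, max_scale)
    tr <- runif(3, -max_trans_mm, max_trans_mm)
    A <- rotation_matrix(ax, ang) %*% diag(sc)
    ctr <- spec$gland_center
    m <- diag(4)
    m[1:3, 1:3] <- A
    m[1:3, 4] <- ctr + tr - A %*% ctr
    t_true <- affine_transform(m, "US", "US")
    moving <- resample_volume(P, P, invert(t_true))
    speckle <- function(v) {
      sh <- spec$appearance$us$speckle_shape
      v$voxels <- v$voxels *
        array(rgamma(length(v$voxels), sh, sh), dim(v$voxels))
      v
    }
    fixed <- speckle(P)
    moving <- speckle(moving)
    fixed_mask <- mask_volume(fixed, list(
      type = "ellipsoid", center = spec$gland_center,
      semiaxes = spec$gland_semiaxes + 6))$mask
    moving_mask <- mask_volume(moving, list(
      type = "ellipsoid",
      center = drop(apply_transform(invert(t_true), spec$gland_center)),
      semiaxes = spec$gland_semiaxes + 8))$mask
    list(fixed = fixed, moving = moving, fixed_mask = fixed_mask,
         moving_mask = moving_mask, t_true = t_true,
         lesion_centers = spec$lesion_centers)
  })
}
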