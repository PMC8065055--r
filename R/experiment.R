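#' Ground truth of a simulated calibration/fusion experiment
#'
#' Defines every transform and noise parameter of a simulated navigation
#' experiment so that all downstream calibrations can be checked against
#' known truth. The world model: the tracker frame is the static world;
#' the imaged object (cone phantom, prostate phantom) is fixed in it; the
#' MR image frame is anchored to the table reference tool at the MR-scan
#' epoch, so after a table shift the tracked shift transform restores that
#' anchor. All tool poses are rigid tool -> tracker maps.
#'
#' @param n_us_obs Number of probe-calibration images (default 5).
#' @param table_shift_mm Length-3 world translation of the table between
#'   the MR scan and the US acquisition (default `c(0, 200, 0)`).
#' @param sigma_tracker Per-axis translational tracker jitter SD in mm
#'   (default 0.3, the middle of the 0.25-0.35 mm static-accuracy class).
#' @param sigma_rot_deg Per-axis rotational tracker jitter SD in degrees
#'   (default 0.05).
#' @param sigma_stylus Per-axis stylus tip localization SD in mm (default
#'   0.3).
#' @param sigma_us_img Per-axis cone-tip localization SD in the US image,
#'   mm (default 1.0).
#' @param sigma_mr_img Per-axis cone-tip localization SD in the MR image,
#'   mm (default 0.5).
#' @param noise_scale Common multiplier applied to all five sigmas
#'   (e.g. 0 for a noiseless experiment).
#' @param phantom A [phantom_spec()] placed in the MR frame.
#' @return An object of class `experiment_truth`.
#' @export
experiment_truth <- function(n_us_obs = 5L,
                             table_shift_mm = c(0, 200, 0),
                             sigma_tracker = 0.3,
                             sigma_rot_deg = 0.05,
                             sigma_stylus = 0.3,
                             sigma_us_img = 1.0,
                             sigma_mr_img = 0.5,
                             noise_scale = 1,
                             phantom = phantom_spec()) {
  noise <- list(sigma_tracker = sigma_tracker * noise_scale,
                sigma_rot_deg = sigma_rot_deg * noise_scale,
                sigma_stylus = sigma_stylus * noise_scale,
                sigma_us_img = sigma_us_img * noise_scale,
                sigma_mr_img = sigma_mr_img * noise_scale)
  stopifnot(all(unlist(noise) >= 0))

  # --- static truth transforms (deterministic, representative geometry)
  t_us_trans <- transform_rigid(
    rotation_matrix(c(1, 0.4, 0.2), 25 * pi / 180),
    c(-12, 8, 95), "US", "trans")
  t_mr_table <- transform_rigid(
    rotation_matrix(c(0.2, 1, 0.5), -35 * pi / 180),
    c(140, -60, 220), "MR", "ORF_TABLE")
  t_cad_tank <- transform_rigid(
    rotation_matrix("z", 15 * pi / 180), c(30, -20, 55), "CAD", "tank")
  # intra-modal TRUS -> US truth: small rotation + shift + anisotropic scale
  A <- rotation_matrix(c(0.3, 0.2, 1), 6 * pi / 180) %*%
    diag(c(1.02, 0.99, 1.015))
  m <- diag(4); m[1:3, 1:3] <- A; m[1:3, 4] <- c(3, -2, 4)
  t_trus_us <- affine_transform(m, "TRUS", "US")

  pose_tank <- transform_rigid(
    rotation_matrix(c(0, 1, 0.3), 40 * pi / 180), c(250, 150, -800), "tank",
    "tracker")
  pose_table <- transform_rigid(
    rotation_matrix(c(1, 0.2, 0), -30 * pi / 180), c(-180, 90, -1050),
    "ORF_TABLE", "tracker")
  pose_gantry <- transform_rigid(
    rotation_matrix(c(0, 0.3, 1), 70 * pi / 180), c(-150, -220, -1200),
    "ORF_MR", "tracker")
  pose_table_after <- compose(
    transform_translation(table_shift_mm, "tracker", "tracker"), pose_table)
  pose_table_after$source <- "ORF_moved"
  pose_probe_acq <- transform_rigid(
    rotation_matrix(c(0.5, 1, 0.1), 55 * pi / 180), c(40, 60, -900),
    "trans", "tracker")
  # varied probe poses for the calibration images
  probe_cal_poses <- lapply(seq_len(n_us_obs), function(k) {
    ang <- (10 + 12 * k) * pi / 180
    ax <- c(cos(0.9 * k), sin(1.3 * k), 0.5 + 0.1 * k)
    off <- c(230 + 12 * k, 120 - 15 * k, -780 - 8 * k)
    transform_rigid(rotation_matrix(ax, ang), off, "trans", "tracker")
  })

  cad_tips <- make_multicone(7L, frame = "CAD")
  tank_tips <- apply_transform(t_cad_tank, cad_tips)
  # independent second cone phantom providing held-out TRE targets
  target_tips <- apply_transform(
    t_cad_tank,
    make_multicone(7L, extent = c(70, 70),
                   heights = 18 + 20 * (((1:7) * 0.414214) %% 1),
                   frame = "CAD"))
  mr_tips <- make_multicone(18L, extent = c(120, 160), frame = "MR")

  truth <- list(
    transforms = list(t_us_trans = t_us_trans, t_mr_table = t_mr_table,
                      t_cad_tank = t_cad_tank, t_trus_us = t_trus_us),
    poses = list(tank = pose_tank, table = pose_table, gantry = pose_gantry,
                 table_after = pose_table_after, probe_acq = pose_probe_acq,
                 probe_cal = probe_cal_poses),
    fiducials = list(cad_tips = cad_tips, tank_tips = tank_tips,
                     target_tips = target_tips, mr_tips = mr_tips),
    phantom = phantom,
    table_shift_mm = table_shift_mm,
    noise = noise)
  class(truth) <- "experiment_truth"

  truth$derived <- list(
    table_link = compose(invert(pose_gantry), pose_table),  # ORF_TABLE -> ORF_MR
    shift = compose(invert(pose_table), pose_table_after),  # ORF_moved -> ORF_TABLE
    t_us_mr = compose(compose(invert(t_mr_table), invert(pose_table)),
                      compose(pose_probe_acq, t_us_trans)))
  truth
}

#' @export
print.experiment_truth <- function(x, ...) {
  cat(sprintf(
    "<experiment_truth> %d calibration images, table shift (%s) mm\n",
    length(x$poses$probe_cal),
    paste(x$table_shift_mm, collapse = ", ")))
  cat("  noise (mm / deg):",
      paste(sprintf("%s=%.3g", names(x$noise), unlist(x$noise)),
            collapse = ", "), "\n")
  invisible(x)
}

# MR-frame coordinates of a world (tracker) point at the MR-scan epoch.
.world_to_mr <- function(truth, xyz) {
  apply_transform(invert(truth$transforms$t_mr_table),
                  apply_transform(invert(truth$poses$table), xyz))
}

# World coordinates of MR-frame points.
.mr_to_world <- function(truth, xyz) {
  apply_transform(truth$poses$table,
                  apply_transform(truth$transforms$t_mr_table, xyz))
}

#' Simulate a complete calibration and fusion experiment
#'
#' Generates every observation the physical workflow would produce, from
#' the ground truth of [experiment_truth()] and its noise parameters:
#' probe-calibration images of the cone-tank phantom (cone tips localized
#' in the US image and by a repeated stylus in the tank frame, with tool
#' poses averaged from jittered tracker streams), the 18-cone MR
#' calibration (repeated stylus readings in the table-tool frame, MR image
#' coordinates), table-shift pose streams, acquisition-epoch pose streams,
#' and ground-truth target coordinates (lesion centroids and held-out cone
#' tips) in every frame. With all sigmas zero, every downstream
#' calibration and the full fusion chain reproduce the truth to numerical
#' precision.
#'
#' @param truth An `experiment_truth`.
#' @param n_stylus_repeats Stylus readings per cone tip for the tank
#'   phantom (default 10).
#' @param n_mr_repeats Stylus readings per tip for the MR phantom
#'   (default 5).
#' @param n_pose_readings Tracker readings per averaged pose epoch
#'   (default 100).
#' @param render_volumes Also render MR- and US-frame phantom volumes
#'   (default `FALSE`; used by image-based registration tests).
#' @param volume_spacing Voxel size for rendered volumes, mm (default
#'   1.5).
#' @param seed Master seed; per-component seeds are derived from it
#'   deterministically.
#' @return An object of class `experiment_bundle`; see Details for the
#'   elements.
#' @details Elements: `us_cal_observations` (input to
#' [calibrate_us_probe()]), `cad_tips`, `mr_cal` (inputs to
#' [calibrate_mr()]), `table_streams` (inputs to [track_table_shift()]),
#' `acquisition` (averaged post-shift poses and their streams), `targets`
#' (fiducial sets of the same physical targets in MR, US and TRUS
#' frames), optional `volumes`, and the generating `truth`.
#' @export
simulate_experiment <- function(truth,
                                n_stylus_repeats = 10L,
                                n_mr_repeats = 5L,
                                n_pose_readings = 100L,
                                render_volumes = FALSE,
                                volume_spacing = 1.5,
                                seed = NULL) {
  stopifnot(inherits(truth, "experiment_truth"))
  seeds <- .derive_seeds(seed, 12L)
  nz <- truth$noise
  tr <- truth$transforms
  po <- truth$poses

  jitter_pose <- function(pose, seed_i) {
    stream <- simulate_tracker(pose, n_pose_readings, nz$sigma_tracker,
                               nz$sigma_rot_deg, seed = seed_i)
    avg <- average_pose(stream)
    avg$source <- pose$source
    list(stream = stream, avg = avg)
  }

  # --- probe calibration observations -----------------------------------
  us_obs <- .with_seed(seeds[[1L]], {
    lapply(seq_along(po$probe_cal), function(k) {
      pose_probe_true <- po$probe_cal[[k]]
      # true US-image coordinates of the tank cone tips for this image
      to_us <- compose(compose(invert(tr$t_us_trans), invert(pose_probe_true)),
                       po$tank)
      image_tips <- .perturb_points(apply_transform(to_us,
                                                    truth$fiducials$tank_tips),
                                    nz$sigma_us_img)
      tank_tips <- .make_repeats(truth$fiducials$tank_tips,
                                 n_stylus_repeats, nz$sigma_stylus)
      list(image_tips = image_tips,
           tank_tips = average_repeats(tank_tips),
           tank_tips_raw = tank_tips,
           pose_probe = jitter_pose(pose_probe_true, NULL)$avg,
           pose_tank = jitter_pose(po$tank, NULL)$avg)
    })
  })

  # --- MR calibration ----------------------------------------------------
  mr_cal_data <- .with_seed(seeds[[2L]], {
    tips_table_true <- apply_transform(tr$t_mr_table,
                                       truth$fiducials$mr_tips)
    list(tips_in_reference = .make_repeats(tips_table_true, n_mr_repeats,
                                           nz$sigma_stylus),
         tips_in_mr = .perturb_points(truth$fiducials$mr_tips,
                                      nz$sigma_mr_img))
  })

  # --- table shift + acquisition epochs ----------------------------------
  before <- simulate_tracker(po$table, n_pose_readings, nz$sigma_tracker,
                             nz$sigma_rot_deg, seed = seeds[[3L]])
  after_pose <- po$table_after
  after_pose$source <- po$table$source   # same physical tool id
  after <- simulate_tracker(after_pose, n_pose_readings, nz$sigma_tracker,
                            nz$sigma_rot_deg, t0 = 60, seed = seeds[[4L]])
  gantry <- jitter_pose(po$gantry, seeds[[5L]])
  table_at_mr <- simulate_tracker(po$table, n_pose_readings,
                                  nz$sigma_tracker, nz$sigma_rot_deg,
                                  seed = seeds[[6L]])
  probe_acq <- jitter_pose(po$probe_acq, seeds[[7L]])
  moved_ref <- simulate_tracker(after_pose, n_pose_readings,
                                nz$sigma_tracker, nz$sigma_rot_deg,
                                t0 = 120, seed = seeds[[8L]])
  moved_ref_avg <- average_pose(moved_ref)
  moved_ref_avg$source <- "ORF_moved"

  # --- ground-truth targets in every frame -------------------------------
  lesion_mr <- fiducial_set(truth$phantom$lesion_centers, "MR",
                            labels = sprintf("lesion%d",
                                             seq_len(nrow(truth$phantom$lesion_centers))))
  world <- .mr_to_world(truth, lesion_mr$points)
  to_us_acq <- compose(invert(tr$t_us_trans), invert(po$probe_acq))
  lesion_us <- fiducial_set(apply_transform(to_us_acq, world), "US",
                            lesion_mr$labels)
  lesion_trus <- fiducial_set(
    apply_transform(invert(tr$t_trus_us), lesion_us$points), "TRUS",
    lesion_mr$labels)
  # held-out cone-tip targets (second phantom in the tank)
  tt <- truth$fiducials$target_tips
  tt_world <- apply_transform(po$tank, tt$points)
  cone_targets_us <- fiducial_set(apply_transform(to_us_acq, tt_world),
                                  "US", tt$labels)
  cone_targets_mr <- fiducial_set(.world_to_mr(truth, tt_world), "MR",
                                  tt$labels)

  volumes <- NULL
  if (render_volumes) {
    volumes <- list(
      mr = render_phantom(truth$phantom, "mr", spacing = volume_spacing,
                          frame = "MR", seed = seeds[[9L]]),
      us = .render_us_from_mr(truth, volume_spacing, seeds[[10L]]))
  }

  structure(list(
    us_cal_observations = us_obs,
    cad_tips = truth$fiducials$cad_tips,
    mr_cal = mr_cal_data,
    table_streams = list(before = before, after = after,
                         table_tool = po$table$source),
    pre_shift = list(gantry = gantry$avg, table = average_pose(table_at_mr)),
    acquisition = list(pose_probe = probe_acq$avg,
                       pose_moved_ref = moved_ref_avg,
                       probe_stream = probe_acq$stream,
                       moved_ref_stream = moved_ref),
    targets = list(lesions_mr = lesion_mr, lesions_us = lesion_us,
                   lesions_trus = lesion_trus,
                   cones_us = cone_targets_us, cones_mr = cone_targets_mr),
    volumes = volumes,
    truth = truth),
    class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf(
    "<experiment_bundle> %d US calibration images, %d MR cal tips, %d lesion + %d cone targets%s\n",
    length(x$us_cal_observations), length(x$mr_cal$tips_in_mr),
    length(x$targets$lesions_mr), length(x$targets$cones_mr),
    if (is.null(x$volumes)) "" else ", volumes rendered"))
  invisible(x)
}

# US-frame volume: phantom geometry carried into the US frame through the
# true chain, rendered by resampling the noiseless MR-frame rendering and
# adding US appearance (speckle, attenuation) in the US frame.
.render_us_from_mr <- function(truth, spacing, seed) {
  t_mr_us <- invert(truth$derived$t_us_mr)        # MR -> US
  ph_mr <- render_phantom(truth$phantom, "us", spacing = spacing,
                          frame = "MR", seed = NULL)  # noiseless US appearance
  # US grid: bounding box of the mapped MR grid corners
  d <- dim(ph_mr$image$voxels) - 1L
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  cw <- apply_transform(t_mr_us, voxel_to_world(ph_mr$image, corners))
  lo <- apply(cw, 2L, min); hi <- apply(cw, 2L, max)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid <- volume_image(array(0, dims), rep(spacing, 3L), lo, frame = "US")
  img <- resample_volume(ph_mr$image, grid, t_mr_us)
  ap <- truth$phantom$appearance$us
  vox <- img$voxels
  gen <- function() {
    depth <- voxel_centers(grid)[, 3] - lo[3]
    att <- exp(-ap$attenuation_per_mm * depth)
    speckle <- rgamma(length(vox), shape = ap$speckle_shape,
                      rate = ap$speckle_shape)
    array(as.numeric(vox) * att * speckle, dims)
  }
  img$voxels <- if (is.null(seed)) gen() else .with_seed(seed, gen())
  masks <- lapply(ph_mr$lesion_masks, resample_volume, fixed_grid = grid,
                  t = t_mr_us, interpolation = "nearest")
  gland <- resample_volume(ph_mr$gland_mask, grid, t_mr_us,
                           interpolation = "nearest")
  list(image = img, gland_mask = gland, lesion_masks = masks,
       spec = truth$phantom)
}

#' Run the full tracked-fusion pipeline on a simulated experiment
#'
#' Executes the complete technical workflow on a bundle from
#' [simulate_experiment()]: probe calibration from the pooled cone-tank
#' observations (optionally CAD-refined tank fiducials), MR calibration
#' from the 18-cone data, table-shift tracking, assembly of the US -> MR
#' chain (with or without table-shift compensation), and TRUS -> MR point
#' mapping of the ground-truth targets, returning the chain and its target
#' registration errors against truth.
#'
#' @param bundle An `experiment_bundle`.
#' @param use_table_shift Build the shift-compensated chain (default
#'   `TRUE`; the simulated acquisition happens after the shift, so this is
#'   the physically correct chain).
#' @param reference `"table"` or `"gantry"`: which reference tool the MR
#'   calibration is expressed against (gantry adds the static table-gantry
#'   link).
#' @param refine_cad Replace stylus-measured tank fiducials by CAD-refined
#'   ones (default `TRUE`).
#' @return List of class `fusion_result`: calibrations, `shift`,
#'   `t_us_mr`, `t_trus_mr`, per-target TREs (`tre_cones`, `tre_lesions`,
#'   `tre_trus`) against ground truth.
#' @export
fuse_experiment <- function(bundle, use_table_shift = TRUE,
                            reference = c("table", "gantry"),
                            refine_cad = TRUE) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  reference <- match.arg(reference)

  obs <- bundle$us_cal_observations
  if (refine_cad) {
    obs <- lapply(obs, function(ob) {
      ob$tank_tips <- refine_fiducials_via_cad(ob$tank_tips,
                                               bundle$cad_tips)
      ob
    })
  }
  probe_cal <- calibrate_us_probe(obs)

  tips_ref <- bundle$mr_cal$tips_in_reference
  if (reference == "gantry") {
    # re-express the stylus tips against the gantry tool via the tracked
    # static link between the two reference tools at the MR-scan epoch
    link <- compose(invert(bundle$pre_shift$gantry), bundle$pre_shift$table)
    tips_ref <- apply_transform(link, tips_ref)
  }
  mr_cal <- calibrate_mr(tips_ref, bundle$mr_cal$tips_in_mr)

  shift <- track_table_shift(bundle$table_streams$before,
                             bundle$table_streams$after,
                             bundle$table_streams$table_tool)

  t_us_mr <- if (use_table_shift) {
    mr_from_us_with_tableshift(
      mr_cal, probe_cal, shift,
      pose_probe_after = bundle$acquisition$pose_probe,
      pose_ref_after = bundle$acquisition$pose_moved_ref,
      table_link = if (reference == "gantry")
        compose(invert(bundle$pre_shift$gantry), bundle$pre_shift$table)
      else NULL)
  } else {
    # valid only when the table did not move: use the MR-epoch reference
    # tool pose with the acquisition-epoch probe pose
    pose_ref <- if (reference == "gantry") bundle$pre_shift$gantry else
      bundle$pre_shift$table
    mr_from_us(mr_cal, bundle$acquisition$pose_probe, pose_ref, probe_cal)
  }

  t_trus_mr <- compose(t_us_mr, bundle$truth$transforms$t_trus_us)

  tre_cones <- compute_tre(bundle$targets$cones_us, bundle$targets$cones_mr,
                           t_us_mr)
  tre_lesions <- compute_tre(bundle$targets$lesions_us,
                             bundle$targets$lesions_mr, t_us_mr)
  tre_trus <- compute_tre(bundle$targets$lesions_trus,
                          bundle$targets$lesions_mr, t_trus_mr)

  structure(list(probe_cal = probe_cal, mr_cal = mr_cal, shift = shift,
                 t_us_mr = t_us_mr, t_trus_mr = t_trus_mr,
                 tre_cones = tre_cones, tre_lesions = tre_lesions,
                 tre_trus = tre_trus),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>\n")
  cat(sprintf("  probe calibration FRE: %.3f mm (%d images)\n",
              x$probe_cal$fre_mm, x$probe_cal$n_images_used))
  cat(sprintf("  MR calibration FRE:    %.3f mm\n", x$mr_cal$fre_mm))
  cat(sprintf("  cone-target TRE:       %.3f +/- %.3f mm (n=%d)\n",
              x$tre_cones$mean_mm, x$tre_cones$sd_mm, x$tre_cones$n))
  cat(sprintf("  lesion TRE (US->MR):   %.3f mm\n", x$tre_lesions$mean_mm))
  cat(sprintf("  lesion TRE (TRUS->MR): %.3f mm\n", x$tre_trus$mean_mm))
  invisible(x)
}

# Deterministic per-component seeds below 2^31 derived from a master seed.
.derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(.with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}
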