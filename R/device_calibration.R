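#' Stylus pivot calibration
#'
#' Recovers the tip offset of a tracked stylus from poses collected while
#' pivoting the tool about a fixed physical point. Solves the algebraic
#' least-squares problem `R_i p_tip + t_i = p_pivot` for the tip in the
#' tool frame and the pivot in the tracker frame simultaneously.
#'
#' @param poses A `pose_stream` of the stylus tool (single tool, valid
#'   readings used).
#' @param tool_id Stylus tool id; default the only tool present.
#' @param min_poses Minimum number of valid poses (default 10).
#' @return List with `tip_tool` (length-3, tool frame, mm), `pivot_tracker`
#'   (length-3, tracker frame, mm), `residual_rms_mm`, and `n_poses`.
#' @export
calibrate_pivot <- function(poses, tool_id = NULL, min_poses = 10L) {
  stopifnot(inherits(poses, "pose_stream"))
  if (is.null(tool_id)) {
    ids <- unique(poses$tool_id)
    if (length(ids) != 1L) stop("several tools present; specify tool_id")
    tool_id <- ids
  }
  s <- filter_tool(poses, tool_id)
  n <- nrow(s)
  if (n < min_poses) {
    stop("pivot calibration needs at least ", min_poses, " valid poses, got ", n)
  }
  A <- matrix(0, 3L * n, 6L)
  b <- numeric(3L * n)
  Rs <- vector("list", n)
  for (i in seq_len(n)) {
    R <- quaternion_to_matrix(c(s$qx[i], s$qy[i], s$qz[i], s$qw[i]))
    Rs[[i]] <- R
    rows <- (3L * (i - 1L) + 1L):(3L * i)
    A[rows, 1:3] <- R
    A[rows, 4:6] <- -diag(3)
    b[rows] <- -c(s$tx[i], s$ty[i], s$tz[i])
  }
  sv <- svd(A)
  # with no orientation variation the problem is rank-deficient: any shift
  # of the tip along the (common) rotation axis trades off against the pivot
  if (sv$d[6] / sv$d[1] < 1e-6) {
    stop("degenerate pivot sweep: poses span too little orientation variation")
  }
  x <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  tip <- x[1:3]
  pivot <- x[4:6]
  res2 <- vapply(seq_len(n), function(i) {
    sum((Rs[[i]] %*% tip + c(s$tx[i], s$ty[i], s$tz[i]) - pivot)^2)
  }, 0)
  list(tip_tool = as.numeric(tip), pivot_tracker = as.numeric(pivot),
       residual_rms_mm = sqrt(mean(res2)), n_poses = n)
}

#' Probe calibration result
#'
#' Container tying the image-to-tool transform of a tracked imaging probe
#' to its registration statistics.
#'
#' @param image_to_tool Rigid `frame_transform` from the image frame to the
#'   probe's tracking-tool frame (e.g. `US -> trans`).
#' @param fre_mm Fiducial registration error of the underlying paired-point
#'   fit (mm).
#' @param n_images_used Number of images pooled into the fit.
#' @param registration Optional underlying `point_registration`.
#' @return An object of class `probe_calibration`.
#' @export
probe_calibration <- function(image_to_tool, fre_mm, n_images_used,
                              registration = NULL) {
  stopifnot(is_frame_transform(image_to_tool), image_to_tool$rigid,
            fre_mm >= 0)
  structure(list(image_to_tool = image_to_tool, fre_mm = fre_mm,
                 n_images_used = n_images_used, registration = registration),
            class = "probe_calibration")
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat(sprintf("<probe_calibration> %s -> %s, FRE %.4f mm (%d image%s)\n",
              x$image_to_tool$source, x$image_to_tool$target, x$fre_mm,
              x$n_images_used, if (x$n_images_used == 1L) "" else "s"))
  invisible(x)
}

#' Spatial calibration of a tracked 3D ultrasound probe
#'
#' Each observation is one 3D US image of the multi-cone water-tank phantom
#' taken at a different probe position/orientation: the cone tips localized
#' in US image coordinates, the same tips known in the tank reference
#' frame, and the tracker poses of the probe tool and the tank tool at
#' acquisition. Tank tips are mapped into the probe-tool frame through
#' `invert(pose_probe) . pose_tank`; pairs are pooled across observations
#' (labels suffixed per observation) and a single paired-point registration
#' yields the image-to-tool transform `T_US^trans`.
#'
#' @param observations List of lists, each with elements `image_tips`
#'   (`fiducial_set` in the image frame), `tank_tips` (`fiducial_set` in
#'   the tank frame), `pose_probe` (rigid, probe tool -> tracker) and
#'   `pose_tank` (rigid, tank tool -> tracker).
#' @param image_frame,tool_frame Frame names for the probe image and tool;
#'   defaults taken from the first observation.
#' @return A `probe_calibration` (`image_to_tool` maps image -> tool).
#' @export
calibrate_us_probe <- function(observations, image_frame = NULL,
                               tool_frame = NULL) {
  if (!length(observations)) stop("at least one observation required")
  img_list <- list(); tool_list <- list()
  for (k in seq_along(observations)) {
    ob <- observations[[k]]
    stopifnot(inherits(ob$image_tips, "fiducial_set"),
              inherits(ob$tank_tips, "fiducial_set"),
              is_frame_transform(ob$pose_probe),
              is_frame_transform(ob$pose_tank))
    if (is.null(image_frame)) image_frame <- ob$image_tips$frame
    if (is.null(tool_frame)) tool_frame <- ob$pose_probe$source
    if (!identical(ob$image_tips$frame, image_frame)) {
      stop(sprintf("observation %d: image tips in frame '%s', expected '%s'",
                   k, ob$image_tips$frame, image_frame))
    }
    # tank -> tracker -> tool
    tank_to_tool <- compose(invert(ob$pose_probe), ob$pose_tank)
    if (!identical(tank_to_tool$source, ob$tank_tips$frame)) {
      stop(sprintf(
        "observation %d: tank pose source '%s' does not match tank tips frame '%s'",
        k, tank_to_tool$source, ob$tank_tips$frame))
    }
    tips_tool <- apply_transform(tank_to_tool, ob$tank_tips)
    labs <- paste0(ob$image_tips$labels, "@", k)
    img_list[[k]] <- fiducial_set(ob$image_tips$points, image_frame, labs)
    common <- ob$image_tips$labels
    if (!setequal(common, ob$tank_tips$labels)) {
      stop(sprintf("observation %d: image and tank tips carry different labels", k))
    }
    tool_list[[k]] <- fiducial_set(tips_tool$points[common, , drop = FALSE],
                                   tool_frame, labs)
  }
  moving <- fiducial_set(do.call(rbind, lapply(img_list, `[[`, "points")),
                         image_frame,
                         unlist(lapply(img_list, `[[`, "labels")))
  fixed <- fiducial_set(do.call(rbind, lapply(tool_list, `[[`, "points")),
                        tool_frame,
                        unlist(lapply(tool_list, `[[`, "labels")))
  reg <- register_points(moving, fixed)
  probe_calibration(reg$transform, reg$fre_mm, length(observations), reg)
}

#' Spatial calibration of a tracked 2D TRUS probe
#'
#' A calibrated pointer is swept through the TRUS image plane; for selected
#' time points the pointer tip is localized both on the image (pixel
#' coordinates) and by the tracker. Pixel coordinates are lifted to image
#' millimetres in the `z = 0` plane (0-based indices at pixel centres),
#' pointer tips are mapped into the probe-tool frame, and a paired-point
#' registration (coplanar-tolerant) yields the image-to-tool transform.
#'
#' @param pixel_points N x 2 matrix of pointer-tip pixel coordinates.
#' @param pixel_spacing Length-2 pixel size in mm.
#' @param pointer_tips_tracker N x 3 matrix of the tip in tracker mm.
#' @param pose_probe Rigid `frame_transform`, probe tool -> tracker, held
#'   fixed during the sweep.
#' @param image_frame Frame name of the TRUS image (default `"TRUS"`).
#' @return A `probe_calibration` with a coplanarity flag in
#'   `$registration$coplanar`.
#' @export
calibrate_trus_probe <- function(pixel_points, pixel_spacing,
                                 pointer_tips_tracker, pose_probe,
                                 image_frame = "TRUS") {
  pixel_points <- as.matrix(pixel_points)
  pointer_tips_tracker <- as.matrix(pointer_tips_tracker)
  stopifnot(ncol(pixel_points) == 2L, length(pixel_spacing) == 2L,
            ncol(pointer_tips_tracker) == 3L,
            nrow(pixel_points) == nrow(pointer_tips_tracker),
            is_frame_transform(pose_probe))
  n <- nrow(pixel_points)
  if (n < 3L) stop("degenerate configuration: at least 3 in-plane points required")
  img_mm <- cbind(pixel_points[, 1] * pixel_spacing[1],
                  pixel_points[, 2] * pixel_spacing[2],
                  0)
  labs <- paste0("P", seq_len(n))
  moving <- fiducial_set(img_mm, image_frame, labs)
  tips_tool <- apply_transform(invert(pose_probe),
                               pointer_tips_tracker)
  fixed <- fiducial_set(tips_tool, pose_probe$source, labs)
  reg <- register_points(moving, fixed)   # errors out if collinear
  probe_calibration(reg$transform, reg$fre_mm, 1L, reg)
}

#' MR calibration result
#'
#' @param mr_to_reference Rigid `frame_transform` from MR image millimetre
#'   coordinates to an optical reference tool frame (table or gantry).
#' @param fre_mm Fiducial registration error (mm).
#' @param reference_frame Which reference tool the calibration refers to
#'   (its frame name, e.g. `"ORF_TABLE"` or `"ORF_MR"`).
#' @param registration Optional underlying `point_registration`.
#' @return An object of class `mr_calibration`.
#' @export
mr_calibration <- function(mr_to_reference, fre_mm,
                           reference_frame = mr_to_reference$target,
                           registration = NULL) {
  stopifnot(is_frame_transform(mr_to_reference), mr_to_reference$rigid,
            fre_mm >= 0)
  structure(list(mr_to_reference = mr_to_reference, fre_mm = fre_mm,
                 reference_frame = reference_frame,
                 registration = registration),
            class = "mr_calibration")
}

#' @export
print.mr_calibration <- function(x, ...) {
  cat(sprintf("<mr_calibration> %s -> %s, FRE %.4f mm\n",
              x$mr_to_reference$source, x$mr_to_reference$target, x$fre_mm))
  invisible(x)
}

#' MR gantry/table calibration from a multi-cone phantom
#'
#' The tips of a multi-cone phantom (18 cones in the reference layout) are
#' measured with a calibrated stylus relative to an optical reference tool
#' mounted on the MR table (repeat readings averaged first), and localized
#' in MR image millimetre coordinates from the MR scan of the same phantom.
#' A paired-point registration of the MR coordinates onto the
#' reference-tool coordinates yields `T_MR^ORF_TABLE` (or `T_MR^ORF_MR`
#' when the gantry tool is used as reference).
#'
#' @param tips_in_reference `fiducial_set` in the reference tool frame,
#'   typically with stylus repeats.
#' @param tips_in_mr `fiducial_set` in MR image mm.
#' @param min_tips Minimum number of paired tips (default 3).
#' @return An `mr_calibration`.
#' @export
calibrate_mr <- function(tips_in_reference, tips_in_mr, min_tips = 3L) {
  stopifnot(inherits(tips_in_reference, "fiducial_set"),
            inherits(tips_in_mr, "fiducial_set"))
  if (length(tips_in_mr) < min_tips) {
    stop("degenerate configuration: at least ", min_tips, " tips required")
  }
  averaged <- average_repeats(tips_in_reference)
  reg <- register_points(tips_in_mr, averaged)
  mr_calibration(reg$transform, reg$fre_mm,
                 reference_frame = averaged$frame, registration = reg)
}

#' Track a table shift between two epochs
#'
#' The MR table moves between the MR scan and the US acquisition; the
#' optical tool on the table is observed before and after. The epoch
#' averages give the rigid motion `T_ORF_moved^ORF_TABLE` mapping
#' coordinates expressed relative to the moved tool back into the
#' before-shift reference frame.
#'
#' @param before,after `pose_stream`s containing the table tool.
#' @param table_tool Tool id of the table reference tool.
#' @param moved_frame Frame name for the post-shift tool frame (default
#'   `"ORF_moved"`); the pre-shift frame keeps the tool's own name.
#' @return A rigid `frame_transform` from `moved_frame` to the tool frame.
#' @export
track_table_shift <- function(before, after, table_tool,
                              moved_frame = "ORF_moved") {
  pb <- average_pose(before, table_tool)   # ORF_TABLE -> tracker
  pa <- average_pose(after, table_tool)    # moved tool -> tracker
  pa$source <- moved_frame
  compose(invert(pb), pa)                  # moved -> ORF_TABLE
}
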