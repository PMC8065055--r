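#' Fuse MR and tracked 3D US frames without table shift
#'
#' Builds the rigid map from US image millimetre coordinates to MR image
#' millimetre coordinates from tracked calibrations alone:
#' `T_US^MR = T_ORF^MR . T_trans^ORF . T_US^trans`, where the middle link
#' is the relative pose of the probe tool with respect to the MR reference
#' tool, both read by the tracker at the US acquisition.
#'
#' @param mr_cal `mr_calibration` (provides `T_MR^ORF`, inverted
#'   internally).
#' @param pose_probe Rigid `frame_transform`, probe tool -> tracker, at US
#'   acquisition.
#' @param pose_ref Rigid `frame_transform`, MR reference tool -> tracker,
#'   same epoch.
#' @param probe_cal `probe_calibration` (provides `T_US^trans`).
#' @return Rigid `frame_transform` US -> MR.
#' @export
mr_from_us <- function(mr_cal, pose_probe, pose_ref, probe_cal) {
  stopifnot(inherits(mr_cal, "mr_calibration"),
            inherits(probe_cal, "probe_calibration"),
            is_frame_transform(pose_probe), is_frame_transform(pose_ref))
  ref_to_mr <- invert(mr_cal$mr_to_reference)         # ORF -> MR
  trans_to_ref <- compose(invert(pose_ref), pose_probe)  # trans -> ORF
  compose(compose(ref_to_mr, trans_to_ref), probe_cal$image_to_tool)
}

#' Fuse MR and tracked 3D US frames across a table shift
#'
#' Between the MR scan and the US acquisition the table (and phantom)
#' moves; the tracked shift of the table reference tool compensates for it.
#' Two equivalent chains are supported, chosen by the reference tool of the
#' MR calibration:
#'
#' * table-referenced calibration (`T_MR^ORF_TABLE`):
#'   `T_US^MR = T_ORF_TABLE^MR . T_ORF_moved^ORF_TABLE . T_trans^ORF_moved . T_US^trans`
#' * gantry-referenced calibration (`T_MR^ORF_MR`), which needs the extra
#'   static link `T_ORF_TABLE^ORF_MR` between the table tool (pre-shift)
#'   and the gantry tool:
#'   `T_US^MR = T_ORF_MR^MR . T_ORF_TABLE^ORF_MR . T_ORF_moved^ORF_TABLE . T_trans^ORF_moved . T_US^trans`
#'
#' With `shift` equal to the identity and identical poses the result equals
#' [mr_from_us()] exactly.
#'
#' @param mr_cal `mr_calibration`, referenced to the table tool or to the
#'   gantry tool.
#' @param probe_cal `probe_calibration`.
#' @param shift Rigid `frame_transform` `ORF_moved -> ORF_TABLE` from
#'   [track_table_shift()].
#' @param pose_probe_after Rigid probe tool -> tracker after the shift.
#' @param pose_ref_after Rigid moved table tool -> tracker after the shift
#'   (its source frame must be the moved frame, i.e. `shift$source`).
#' @param table_link Rigid `ORF_TABLE -> ORF_MR`; required iff `mr_cal` is
#'   gantry-referenced.
#' @return Rigid `frame_transform` US -> MR.
#' @export
mr_from_us_with_tableshift <- function(mr_cal, probe_cal, shift,
                                       pose_probe_after, pose_ref_after,
                                       table_link = NULL) {
  stopifnot(inherits(mr_cal, "mr_calibration"),
            inherits(probe_cal, "probe_calibration"),
            is_frame_transform(shift),
            is_frame_transform(pose_probe_after),
            is_frame_transform(pose_ref_after))
  if (!identical(pose_ref_after$source, shift$source)) {
    stop(sprintf(
      "frame chain mismatch: post-shift reference pose is for frame '%s' but the shift maps '%s' -> '%s'",
      pose_ref_after$source, shift$source, shift$target))
  }
  ref_to_mr <- invert(mr_cal$mr_to_reference)   # table or gantry ref -> MR
  if (identical(mr_cal$reference_frame, shift$target)) {
    head <- ref_to_mr                            # ORF_TABLE -> MR
  } else {
    if (is.null(table_link)) {
      stop("gantry-referenced MR calibration needs the table_link ",
           "transform (ORF_TABLE -> ORF_MR)")
    }
    head <- compose(ref_to_mr, table_link)       # ORF_TABLE -> MR via gantry
  }
  trans_to_moved <- compose(invert(pose_ref_after), pose_probe_after)
  compose(compose(compose(head, shift), trans_to_moved),
          probe_cal$image_to_tool)
}

#' Map points from the TRUS frame into the MR frame
#'
#' The full fusion mapping `P_MR = T_US^MR . T_TRUS^US . P_TRUS`: the
#' image-based intra-modal affine takes TRUS points into the abdominal US
#' frame, and the tracked calibration chain takes them on into MR.
#'
#' @param points `fiducial_set` in the TRUS frame, or N x 3 matrix.
#' @param t_us_mr Rigid `frame_transform` US -> MR ([mr_from_us()] or
#'   [mr_from_us_with_tableshift()]).
#' @param t_trus_us `frame_transform` TRUS -> US (usually the affine from
#'   [register_affine()]).
#' @return Points in the MR frame, same shape/labels as the input.
#' @export
map_points_trus_to_mr <- function(points, t_us_mr, t_trus_us) {
  full <- compose(t_us_mr, t_trus_us)
  if (is.matrix(points) || is.null(dim(points))) {
    return(apply_transform(full, points))
  }
  apply_transform(full, points)
}

#' Resample a volume onto another grid through a transform
#'
#' Pulls `moving` onto the voxel grid of `fixed_grid`: every fixed voxel
#' centre is mapped through `invert(t)` into the moving volume and
#' interpolated (trilinear for images, nearest-neighbour for label masks or
#' on request), with `fill` outside the moving extent.
#'
#' @param moving `volume_image` in `t$source` frame.
#' @param fixed_grid `volume_image` whose grid (and frame, `t$target`)
#'   defines the output.
#' @param t `frame_transform` moving frame -> fixed frame.
#' @param interpolation `"linear"` or `"nearest"`; default nearest for
#'   `label_mask` inputs, linear otherwise.
#' @param fill Value outside the moving volume (default 0).
#' @return A `volume_image` (or `label_mask`) on the fixed grid.
#' @export
resample_volume <- function(moving, fixed_grid, t,
                            interpolation = NULL, fill = 0) {
  stopifnot(is_volume(moving), is_volume(fixed_grid), is_frame_transform(t))
  if (!identical(t$source, moving$frame)) {
    stop(sprintf("frame mismatch: moving volume in '%s', transform maps '%s' -> '%s'",
                 moving$frame, t$source, t$target))
  }
  if (!identical(t$target, fixed_grid$frame)) {
    stop(sprintf("frame mismatch: fixed grid in '%s', transform targets '%s'",
                 fixed_grid$frame, t$target))
  }
  is_mask <- inherits(moving, "label_mask")
  if (is.null(interpolation)) {
    interpolation <- if (is_mask) "nearest" else "linear"
  }
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  world_fixed <- voxel_centers(fixed_grid)
  world_moving <- apply_transform(invert(t), world_fixed)
  idx <- world_to_voxel(moving, world_moving)
  vals <- if (interpolation == "linear") {
    cpp_trilinear(as.numeric(moving$voxels), dim(moving$voxels), idx, fill)
  } else {
    cpp_nearest(as.numeric(moving$voxels), dim(moving$voxels), idx, fill)
  }
  vox <- array(vals, dim = dim(fixed_grid$voxels))
  out <- volume_image(vox, fixed_grid$spacing, fixed_grid$origin,
                      fixed_grid$direction, fixed_grid$frame)
  if (is_mask) class(out) <- c("label_mask", "volume_image")
  out
}

#' Fuse two volumes for display
#'
#' Resamples `moving` onto the grid of `fixed_grid` through `t` and
#' combines the two: `"overlay"` alpha-blends (`alpha * moving_resampled +
#' (1 - alpha) * fixed`), `"checkerboard"` interleaves cubic tiles of the
#' two volumes.
#'
#' @inheritParams resample_volume
#' @param mode `"overlay"` or `"checkerboard"`.
#' @param alpha Overlay weight of the moving image (default 0.5).
#' @param tile Checkerboard tile edge in voxels (default 8).
#' @return A `volume_image` on the fixed grid.
#' @export
fuse_volumes <- function(moving, fixed_grid, t, mode = c("overlay",
                                                         "checkerboard"),
                         alpha = 0.5, tile = 8L) {
  mode <- match.arg(mode)
  res <- resample_volume(moving, fixed_grid, t, interpolation = "linear")
  d <- dim(fixed_grid$voxels)
  vox <- if (mode == "overlay") {
    alpha * res$voxels + (1 - alpha) * fixed_grid$voxels
  } else {
    tile <- max(1L, as.integer(tile))
    parity <- outer(outer((seq_len(d[1]) - 1L) %/% tile,
                          (seq_len(d[2]) - 1L) %/% tile, `+`),
                    (seq_len(d[3]) - 1L) %/% tile, `+`) %% 2L
    ifelse(parity == 0L, fixed_grid$voxels, res$voxels)
  }
  volume_image(array(vox, d), fixed_grid$spacing, fixed_grid$origin,
               fixed_grid$direction, fixed_grid$frame)
}
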