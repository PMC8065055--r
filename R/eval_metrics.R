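# Surface (boundary) voxel centres of a mask, in world mm. Boundary =
# face-connected definition: mask voxels with at least one 6-neighbour
# outside the mask (or outside the grid).
.surface_points <- function(m) {
  stopifnot(is_volume(m))
  idx <- cpp_boundary_voxels(as.numeric(m$voxels), dim(m$voxels))
  if (nrow(idx) == 0L) stop("mask is empty (no foreground voxels)")
  voxel_to_world(m, idx)
}

.check_same_grid <- function(a, b, what) {
  if (!same_grid(a, b)) {
    stop(what, " requires both masks on the same voxel grid; resample one ",
         "onto the other first (resample_volume with nearest-neighbour)")
  }
}

#' Dice overlap of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)` over masks on the same grid.
#'
#' @param a,b `label_mask` objects (same grid).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(is_volume(a), is_volume(b))
  .check_same_grid(a, b, "dice")
  av <- a$voxels > 0.5
  bv <- b$voxels > 0.5
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0L) stop("Dice is undefined: both masks are empty")
  2 * sum(av & bv) / (na + nb)
}

#' Hausdorff distance between two mask surfaces
#'
#' The exact (maximum) symmetric Hausdorff distance between the
#' face-connected boundary voxel centres of the two masks, in mm.
#'
#' @param a,b Non-empty `label_mask` objects (same grid).
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b) {
  .check_same_grid(a, b, "hausdorff")
  sa <- .surface_points(a)
  sb <- .surface_points(b)
  max(max(cpp_nearest_dists(sa, sb)), max(cpp_nearest_dists(sb, sa)))
}

#' Mean boundary distance between two mask surfaces
#'
#' Symmetrized mean nearest-surface distance: the average of the two
#' directed means over boundary voxel centres. Directed values are
#' reported as attributes `directed_ab` / `directed_ba`.
#'
#' @param a,b Non-empty `label_mask` objects (same grid).
#' @return Mean boundary distance in mm.
#' @export
mean_boundary_distance <- function(a, b) {
  .check_same_grid(a, b, "mean_boundary_distance")
  sa <- .surface_points(a)
  sb <- .surface_points(b)
  dab <- mean(cpp_nearest_dists(sa, sb))
  dba <- mean(cpp_nearest_dists(sb, sa))
  out <- (dab + dba) / 2
  attr(out, "directed_ab") <- dab
  attr(out, "directed_ba") <- dba
  out
}

#' Full overlap report for two masks
#'
#' Convenience wrapper computing Dice, Hausdorff and mean boundary
#' distance in one pass; if the grids differ, `b` is resampled onto `a`'s
#' grid with nearest-neighbour interpolation first (recorded in the
#' report).
#'
#' @param a,b `label_mask` objects.
#' @param t Optional `frame_transform` mapping `b`'s frame onto `a`'s
#'   frame before comparison.
#' @return List of class `overlap_report`: `dice`, `hausdorff_mm`,
#'   `mean_boundary_distance_mm`, `directed_mbd_mm`, `resampled`.
#' @export
overlap_report <- function(a, b, t = NULL) {
  stopifnot(is_volume(a), is_volume(b))
  resampled <- FALSE
  if (!is.null(t)) {
    b <- resample_volume(b, a, t, interpolation = "nearest")
    resampled <- TRUE
  } else if (!same_grid(a, b)) {
    if (!identical(a$frame, b$frame)) {
      stop("masks live in different frames '", a$frame, "' and '", b$frame,
           "'; supply the transform t")
    }
    b <- resample_volume(b, a, transform_identity(b$frame),
                         interpolation = "nearest")
    resampled <- TRUE
  }
  mbd <- mean_boundary_distance(a, b)
  structure(list(dice = dice(a, b),
                 hausdorff_mm = hausdorff(a, b),
                 mean_boundary_distance_mm = as.numeric(mbd),
                 directed_mbd_mm = c(ab = attr(mbd, "directed_ab"),
                                     ba = attr(mbd, "directed_ba")),
                 resampled = resampled),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> Dice %.4f | Hausdorff %.3f mm | mean boundary distance %.3f mm%s\n",
    x$dice, x$hausdorff_mm, x$mean_boundary_distance_mm,
    if (x$resampled) " (b resampled onto a)" else ""))
  invisible(x)
}

# Voxel-centroid (world mm) of a binary mask.
.mask_centroid <- function(m) {
  idx <- which(m$voxels > 0.5, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stop("mask is empty (no foreground voxels)")
  colMeans(voxel_to_world(m, idx))
}

#' Lesion-centroid target registration error
#'
#' For paired lesion masks (same label in both modalities), maps the
#' centroid of each `a` lesion through `t` and reports its Euclidean
#' distance to the centroid of the matching `b` lesion.
#'
#' @param lesions_a,lesions_b Named lists of `label_mask`s (paired by
#'   name).
#' @param t `frame_transform` from the `a` frame to the `b` frame
#'   (default identity).
#' @return List with `per_lesion_mm` (named), `mean_mm`, `sd_mm`, `n`.
#' @export
lesion_centroid_tre <- function(lesions_a, lesions_b, t = NULL) {
  stopifnot(is.list(lesions_a), is.list(lesions_b))
  labs <- names(lesions_a)
  if (is.null(labs) || is.null(names(lesions_b)) ||
      !setequal(labs, names(lesions_b)) ||
      length(labs) != length(lesions_b)) {
    stop("lesion lists must be named and carry the same labels")
  }
  d <- vapply(labs, function(lab) {
    ca <- .mask_centroid(lesions_a[[lab]])
    if (!is.null(t)) ca <- apply_transform(t, ca)
    cb <- .mask_centroid(lesions_b[[lab]])
    sqrt(sum((ca - cb)^2))
  }, 0)
  list(per_lesion_mm = d, mean_mm = mean(d),
       sd_mm = if (length(d) > 1L) sd(d) else NA_real_,
       n = length(d))
}

#' Peak signal-to-noise ratio between two volumes
#'
#' `PSNR = 10 log10(peak^2 / MSE)` in dB, over volumes on the same grid.
#' Identical volumes (MSE 0) return `Inf` with attribute
#' `identical = TRUE`.
#'
#' @param a,b `volume_image` objects on the same grid.
#' @param peak Peak signal value (> 0); default the maximum of `a`.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = NULL) {
  stopifnot(is_volume(a), is_volume(b))
  .check_same_grid(a, b, "psnr")
  if (is.null(peak)) peak <- max(a$voxels)
  if (!is.finite(peak) || peak <= 0) stop("peak must be positive")
  mse <- mean((a$voxels - b$voxels)^2)
  if (mse == 0) {
    out <- Inf
    attr(out, "identical") <- TRUE
    return(out)
  }
  10 * log10(peak^2 / mse)
}
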