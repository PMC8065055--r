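#' Paired-point rigid registration (least squares, SVD)
#'
#' Estimates the rigid transform mapping `moving` onto `fixed` by the
#' closed-form least-squares method: centre both sets, take the SVD of the
#' covariance of the paired centred coordinates, and correct the sign of the
#' last singular vector so the recovered rotation is proper (no reflection),
#' which also handles coplanar fiducial configurations such as an in-plane
#' TRUS calibration sweep. Correspondence is by label: both sets must carry
#' the same labels (order may differ).
#'
#' The fiducial registration error is the RMS residual
#' `FRE = sqrt(mean(||T m_i - f_i||^2))`. Under isotropic fiducial
#' localization error with 3D RMS magnitude FLE applied to one set, the
#' expectation `E[FRE^2] = (1 - 2/N) * FLE^2` holds and is used as a test
#' oracle.
#'
#' @param moving,fixed `fiducial_set` objects with identical labels, at
#'   least 3 non-collinear points.
#' @return An object of class `point_registration`: list with `transform`
#'   (rigid, `moving$frame -> fixed$frame`), `fre_mm`,
#'   `per_point_residuals_mm` (named), `n`, and `coplanar` (logical flag,
#'   `TRUE` when the pooled geometry is planar within tolerance).
#' @examples
#' fixed <- fiducial_set(rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10)), "tank")
#' mv <- apply_transform(transform_translation(c(1, 2, 3), "tank", "img"),
#'                       fixed)
#' reg <- register_points(mv, fixed)
#' reg$fre_mm
#' @export
register_points <- function(moving, fixed) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  if (!setequal(moving$labels, fixed$labels) ||
      length(moving$labels) != length(fixed$labels)) {
    stop("moving and fixed sets must carry the same labels")
  }
  labs <- moving$labels
  M <- moving$points[labs, , drop = FALSE]
  F <- fixed$points[labs, , drop = FALSE]
  n <- nrow(M)
  if (n < 3L) stop("degenerate configuration: at least 3 fiducials required")

  mbar <- colMeans(M); fbar <- colMeans(F)
  Mc <- sweep(M, 2L, mbar); Fc <- sweep(F, 2L, fbar)
  # collinearity / coplanarity from the singular spectrum of the moving set
  sv <- svd(Mc, nu = 0, nv = 0)$d
  scale_ref <- max(sv[1], 1e-12)
  if (sv[2] / scale_ref < 1e-8) {
    stop("degenerate configuration: fiducials are collinear")
  }
  coplanar <- sv[3] / scale_ref < 1e-8

  H <- crossprod(Mc, Fc)               # sum over i of m_i f_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- fbar - R %*% mbar

  mat <- diag(4)
  mat[1:3, 1:3] <- R
  mat[1:3, 4] <- tr
  transform <- rigid_transform(mat, moving$frame, fixed$frame)

  res <- sqrt(rowSums((apply_transform(transform, M) - F)^2))
  out <- list(transform = transform,
              fre_mm = sqrt(mean(res^2)),
              per_point_residuals_mm = res,
              n = n,
              coplanar = coplanar,
              labels = labs)
  class(out) <- "point_registration"
  out
}

#' @export
print.point_registration <- function(x, ...) {
  cat(sprintf("Paired-point rigid registration: %s -> %s\n",
              x$transform$source, x$transform$target))
  cat(sprintf("  n = %d fiducials%s, FRE = %.4f mm\n", x$n,
              if (x$coplanar) " (coplanar)" else "", x$fre_mm))
  invisible(x)
}

#' @export
summary.point_registration <- function(object, ...) {
  cat(sprintf("Paired-point rigid registration: %s -> %s\n",
              object$transform$source, object$transform$target))
  cat(sprintf("  fiducials: %d%s\n", object$n,
              if (object$coplanar) " (coplanar set; det-corrected)" else ""))
  cat(sprintf("  FRE: %.4f mm  (residual range %.4f - %.4f mm)\n",
              object$fre_mm, min(object$per_point_residuals_mm),
              max(object$per_point_residuals_mm)))
  print(object$transform)
  invisible(object)
}

#' @export
coef.point_registration <- function(object, ...) object$transform$matrix

#' @export
residuals.point_registration <- function(object, ...) {
  object$per_point_residuals_mm
}

#' Target registration error at held-out points
#'
#' Maps `targets_moving` through `t` and reports the Euclidean distance of
#' each mapped target to its label-paired counterpart in `targets_fixed`.
#' Targets must be disjoint from the fiducials that produced `t` for the
#' result to be a genuine TRE.
#'
#' @param targets_moving,targets_fixed `fiducial_set` objects with paired
#'   labels, in `t$source` and `t$target` frames respectively.
#' @param t A `frame_transform` mapping moving to fixed.
#' @return List with `per_target_mm` (named), `mean_mm`, `sd_mm`, `n`.
#' @export
compute_tre <- function(targets_moving, targets_fixed, t) {
  stopifnot(inherits(targets_moving, "fiducial_set"),
            inherits(targets_fixed, "fiducial_set"),
            is_frame_transform(t))
  labs <- targets_moving$labels
  if (!setequal(labs, targets_fixed$labels) ||
      length(labs) != length(targets_fixed$labels)) {
    stop("unpaired target labels between the two sets")
  }
  mapped <- apply_transform(t, targets_moving$points[labs, , drop = FALSE])
  d <- sqrt(rowSums((mapped - targets_fixed$points[labs, , drop = FALSE])^2))
  list(per_target_mm = d,
       mean_mm = mean(d),
       sd_mm = if (length(d) > 1L) sd(d) else NA_real_,
       n = length(d))
}

#' Refine measured fiducials from a CAD model
#'
#' The stylus-measured cone-tip coordinates in the tank reference frame are
#' noisy; the CAD model of the calibration phantom gives the same tips
#' noiselessly in its own frame. This registers the CAD tips onto the
#' measured tips and replaces the measured coordinates by the mapped CAD
#' coordinates, reducing per-tip noise to the (much smaller) rigid-fit
#' error.
#'
#' @param measured_tank `fiducial_set` of stylus-measured tips (tank frame).
#' @param cad `fiducial_set` of the same tips in the CAD frame (noiseless).
#' @return A `fiducial_set` in the tank frame (the mapped CAD tips) with
#'   attributes `cad_fit_fre_mm` and `cad_to_tank` (the fitted transform).
#' @export
refine_fiducials_via_cad <- function(measured_tank, cad) {
  reg <- register_points(cad, measured_tank)
  refined <- apply_transform(reg$transform, cad)
  attr(refined, "cad_fit_fre_mm") <- reg$fre_mm
  attr(refined, "cad_to_tank") <- reg$transform
  refined
}
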