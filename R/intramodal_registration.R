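#' Mask a volume to a region of interest
#'
#' Reduces a volume to the region containing the organ of interest, as done
#' manually before intra-modal US/US registration: voxels outside the ROI
#' are zeroed and a companion binary mask is returned. The ROI is given in
#' world millimetres as a box or an ellipsoid.
#'
#' @param v A `volume_image`.
#' @param roi A list, either `list(type = "box", lower, upper)` (corner
#'   coordinates in mm) or `list(type = "ellipsoid", center, semiaxes)`.
#' @return List with `image` (masked `volume_image`) and `mask`
#'   (`label_mask` on the same grid).
#' @export
mask_volume <- function(v, roi) {
  stopifnot(is_volume(v), is.list(roi), !is.null(roi$type))
  ctr <- voxel_centers(v)
  inside <- switch(match.arg(roi$type, c("box", "ellipsoid")),
    box = {
      stopifnot(length(roi$lower) == 3L, length(roi$upper) == 3L)
      ctr[, 1] >= roi$lower[1] & ctr[, 1] <= roi$upper[1] &
        ctr[, 2] >= roi$lower[2] & ctr[, 2] <= roi$upper[2] &
        ctr[, 3] >= roi$lower[3] & ctr[, 3] <= roi$upper[3]
    },
    ellipsoid = {
      stopifnot(length(roi$center) == 3L, length(roi$semiaxes) == 3L,
                all(roi$semiaxes > 0))
      u <- sweep(ctr, 2L, roi$center)
      (u[, 1] / roi$semiaxes[1])^2 + (u[, 2] / roi$semiaxes[2])^2 +
        (u[, 3] / roi$semiaxes[3])^2 <= 1
    })
  if (!any(inside)) stop("ROI does not intersect the volume extent")
  d <- dim(v$voxels)
  mvox <- array(as.numeric(inside), d)
  img <- v
  img$voxels <- v$voxels * mvox
  list(image = img,
       mask = label_mask(mvox, v$spacing, v$origin, v$direction, v$frame))
}

# Robust intensity range used for histogram binning.
.robust_range <- function(x, probs = c(0.005, 0.995)) {
  r <- unname(quantile(x, probs, names = FALSE, type = 7))
  if (r[2] <= r[1]) r[2] <- r[1] + 1e-12
  r
}

# Map intensities to continuous bin coordinates in [0, bins - 1].
.bin_coords <- function(x, rng, bins) {
  b <- (x - rng[1]) / (rng[2] - rng[1]) * (bins - 1)
  pmin.int(pmax.int(b, 0), bins - 1)
}

# MI in nats from a (possibly unnormalized) joint histogram.
.mi_from_hist <- function(H) {
  n <- sum(H)
  if (n <= 0) stop("empty joint histogram")
  p <- H / n
  pf <- rowSums(p); pm <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pf, pm)[nz]))
}

.hist_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two volumes under a transform
#'
#' Mattes-style mutual information (nats) from the joint intensity
#' histogram: sample points are the in-mask voxel centres of `fixed`,
#' mapped through `invert(t)` into `moving` and interpolated trilinearly;
#' each sample contributes to the joint histogram with partial-volume
#' (bilinear Parzen) weights over the adjacent intensity bins. Histogram
#' ranges are the robust 0.5th-99.5th percentile ranges of the two in-mask
#' images.
#'
#' @param fixed,moving `volume_image` objects.
#' @param t `frame_transform` moving frame -> fixed frame (default
#'   identity between their frames).
#' @param bins Number of histogram bins per image (>= 8, default 32).
#' @param fixed_mask,moving_mask Optional `label_mask`s restricting the
#'   samples / the usable moving support.
#' @return MI in nats (non-negative), with attributes `n_samples` and
#'   `h_fixed`/`h_moving` (marginal entropies over the overlap).
#' @export
mutual_information <- function(fixed, moving, t = NULL, bins = 32L,
                               fixed_mask = NULL, moving_mask = NULL) {
  stopifnot(is_volume(fixed), is_volume(moving))
  bins <- as.integer(bins)
  if (bins < 8L) stop("bins must be >= 8")
  if (is.null(t)) t <- transform_identity(moving$frame, fixed$frame)
  sel <- if (is.null(fixed_mask)) TRUE else as.logical(fixed_mask$voxels > 0.5)
  fvals_all <- as.numeric(fixed$voxels)[sel]
  world <- voxel_centers(fixed)
  world <- world[sel, , drop = FALSE]
  rng_f <- .robust_range(fvals_all)
  mv <- if (is.null(moving_mask)) as.numeric(moving$voxels) else
    as.numeric(moving$voxels)[as.logical(moving_mask$voxels > 0.5)]
  rng_m <- .robust_range(mv)
  res <- .mi_sampled(fvals_all, world, moving, t, bins, rng_f, rng_m,
                     moving_mask)
  out <- res$mi
  attr(out, "n_samples") <- res$n
  attr(out, "h_fixed") <- res$h_fixed
  attr(out, "h_moving") <- res$h_moving
  out
}

# Core MI evaluation on precomputed fixed samples. Returns mi and the
# number of overlapping samples; errors if the overlap is empty.
.mi_sampled <- function(fvals, world_fixed, moving, t, bins, rng_f, rng_m,
                        moving_mask = NULL, min_overlap = 10L) {
  idx <- world_to_voxel(moving, apply_transform(invert(t), world_fixed))
  mvals <- cpp_trilinear(as.numeric(moving$voxels), dim(moving$voxels),
                         idx, NA_real_)
  keep <- !is.na(mvals)
  if (!is.null(moving_mask)) {
    inm <- cpp_nearest(as.numeric(moving_mask$voxels),
                       dim(moving_mask$voxels), idx, 0)
    keep <- keep & inm > 0.5
  }
  n <- sum(keep)
  if (n < min_overlap) {
    stop("empty (or near-empty) overlap between the two volumes under the transform")
  }
  fb <- .bin_coords(fvals[keep], rng_f, bins)
  mb <- .bin_coords(mvals[keep], rng_m, bins)
  H <- cpp_joint_hist_pv(fb, mb, bins)
  list(mi = .mi_from_hist(H), n = n,
       h_fixed = .hist_entropy(rowSums(H)),
       h_moving = .hist_entropy(colSums(H)))
}

# ---- affine parameterization -------------------------------------------
# 12 parameters: translation (mm), rotation (rad, xyz Euler), log-scales,
# shears; the linear part acts about a fixed centre c (world mm):
#   x_fixed = R S(hear) S(cale) (x_moving - c) + c + t
.affine_from_params <- function(p, center, source, target) {
  R <- rotation_matrix("x", p[4]) %*% rotation_matrix("y", p[5]) %*%
    rotation_matrix("z", p[6])
  S <- diag(exp(p[7:9]))
  Sh <- diag(3)
  Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  A <- R %*% Sh %*% S
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center + p[1:3] - A %*% center
  affine_transform(m, source, target)
}

# Gaussian smoothing along one array axis via stats::filter on a matrix
# whose columns run along that axis (edge replication padding).
.smooth_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dm <- dim(x)
  m <- matrix(x, nrow = dm[1])
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(nrow(m), r), , drop = FALSE])
  sm <- stats::filter(padded, k, sides = 2)
  sm <- sm[(r + 1L):(r + nrow(m)), , drop = FALSE]
  out <- array(as.numeric(sm), dm)
  aperm(out, order(perm))
}

.gauss_smooth <- function(arr, sigma_vox) {
  for (ax in 1:3) arr <- .smooth_axis(arr, sigma_vox, ax)
  arr
}

# Smooth + stride-downsample a volume by integer factor, keeping geometry.
# At factor 1 a mild smoothing (smooth_vox voxels) suppresses speckle noise
# in the metric without moving structure boundaries.
.downsample_volume <- function(v, factor, smooth_vox = 0.75) {
  if (factor <= 1L) {
    if (smooth_vox > 0) v$voxels <- .gauss_smooth(v$voxels, smooth_vox)
    return(v)
  }
  vox <- .gauss_smooth(v$voxels, factor / 2)
  d <- dim(vox)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  iz <- seq(1L, d[3], by = factor)
  volume_image(vox[ix, iy, iz, drop = FALSE], v$spacing * factor,
               v$origin, v$direction, v$frame)
}

.downsample_mask <- function(m, factor) {
  if (factor <= 1L) return(m)
  d <- dim(m$voxels)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  iz <- seq(1L, d[3], by = factor)
  label_mask(m$voxels[ix, iy, iz, drop = FALSE], m$spacing * factor,
             m$origin, m$direction, m$frame)
}

#' Affine registration by mutual-information maximization
#'
#' Registers `moving` onto `fixed` with a 12-parameter affine transform
#' maximizing Mattes-style mutual information, the intra-modal step that
#' aligns the pre-procedure abdominal 3D-US with the 3D-TRUS volume. The
#' optimization is multi-resolution (downsampling x4 / x2 / x1 with
#' matched Gaussian smoothing) with a derivative-free Nelder-Mead search at
#' each level, centred at the fixed-mask centroid. All in-mask voxels are
#' sampled at the coarser levels; at full resolution a seeded random 25%
#' sample is used, making the result deterministic given `seed` and the
#' inputs.
#'
#' @param fixed,moving `volume_image` objects (the result maps
#'   `moving$frame -> fixed$frame`).
#' @param fixed_mask,moving_mask Optional `label_mask`s (ROI masking).
#' @param init Optional initial `frame_transform` moving -> fixed; default
#'   identity. Only rigid/affine initializations expressible in the
#'   centred 12-parameter model are supported exactly; a general `init` is
#'   converted to starting parameters by polar decomposition.
#' @param bins Histogram bins (default 32).
#' @param levels Downsampling factors, coarse to fine (default
#'   `c(4, 2, 1)`).
#' @param sample_fraction Fraction of in-mask voxels sampled at the finest
#'   level (default 0.25).
#' @param maxit Nelder-Mead iteration cap per level (default
#'   `c(400, 300, 200)` matched to `levels`).
#' @param seed Integer seed for the fine-level sample (default 1).
#' @return List of class `affine_registration`: `transform` (affine
#'   `frame_transform`), `mi` (final MI, nats), `mi_init`, `params`,
#'   `center`, `report` (per-level data frame), `converged`.
#' @export
register_affine <- function(fixed, moving, fixed_mask = NULL,
                            moving_mask = NULL, init = NULL, bins = 32L,
                            levels = c(4L, 2L, 1L),
                            sample_fraction = 0.25,
                            maxit = NULL, seed = 1L) {
  stopifnot(is_volume(fixed), is_volume(moving))
  if (is.null(maxit)) {
    maxit <- round(seq(400, 200, length.out = length(levels)))
  }
  maxit <- rep_len(maxit, length(levels))
  # centre of rotation: fixed-mask centroid (world mm)
  sel <- if (is.null(fixed_mask)) rep(TRUE, length(fixed$voxels)) else
    as.logical(fixed_mask$voxels > 0.5)
  world_all <- voxel_centers(fixed)
  center <- colMeans(world_all[sel, , drop = FALSE])

  p <- numeric(12L)
  if (!is.null(init)) {
    stopifnot(is_frame_transform(init))
    p <- .params_from_affine(init$matrix, center)
  }
  rng_f <- .robust_range(as.numeric(fixed$voxels)[sel])
  mv_sel <- if (is.null(moving_mask)) as.numeric(moving$voxels) else
    as.numeric(moving$voxels)[as.logical(moving_mask$voxels > 0.5)]
  rng_m <- .robust_range(mv_sel)

  parscale <- c(rep(1, 3), rep(0.02, 3), rep(0.02, 3), rep(0.02, 3))
  report <- NULL
  mi_global_init <- NA_real_
  p_init <- p
  for (li in seq_along(levels)) {
    f <- as.integer(levels[li])
    fx <- .downsample_volume(fixed, f)
    mvg <- .downsample_volume(moving, f)
    fmk <- if (is.null(fixed_mask)) NULL else .downsample_mask(fixed_mask, f)
    mmk <- if (is.null(moving_mask)) NULL else .downsample_mask(moving_mask, f)
    sel_l <- if (is.null(fmk)) rep(TRUE, length(fx$voxels)) else
      as.logical(fmk$voxels > 0.5)
    fvals <- as.numeric(fx$voxels)[sel_l]
    world <- voxel_centers(fx)[sel_l, , drop = FALSE]
    if (f == 1L && sample_fraction < 1) {
      n_take <- max(1000L, ceiling(sample_fraction * nrow(world)))
      n_take <- min(n_take, nrow(world))
      take <- .with_seed(seed, sample.int(nrow(world), n_take))
      fvals <- fvals[take]
      world <- world[take, , drop = FALSE]
    }
    objective <- function(par) {
      t <- tryCatch(
        .affine_from_params(par, center, moving$frame, fixed$frame),
        error = function(e) NULL)
      if (is.null(t)) return(1e6)
      res <- tryCatch(
        .mi_sampled(fvals, world, mvg, t, bins, rng_f, rng_m, mmk),
        error = function(e) NULL)
      if (is.null(res)) return(1e6)
      -res$mi
    }
    mi0 <- -objective(p)
    if (li == 1L) mi_global_init <- mi0
    # Nelder-Mead with one restart: re-running from the first optimum with
    # a fresh simplex recovers the well-known NM premature-collapse cases
    best_val <- -mi0
    evals <- 0L
    for (pass in 1:2) {
      fit <- optim(p, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit[li], parscale = parscale,
                                  reltol = 1e-9))
      evals <- evals + fit$counts[["function"]]
      if (fit$value < best_val) {
        p <- fit$par
        best_val <- fit$value
      }
    }
    report <- rbind(report, data.frame(
      level = li, factor = f, n_samples = length(fvals),
      mi_init = mi0, mi_final = -best_val, evals = evals))
  }
  # final guard at full resolution: never return worse than the init
  final_obj <- function(par) {
    t <- .affine_from_params(par, center, moving$frame, fixed$frame)
    res <- .mi_sampled(
      as.numeric(fixed$voxels)[sel],
      world_all[sel, , drop = FALSE], moving, t, bins, rng_f, rng_m,
      moving_mask)
    res$mi
  }
  mi_init_full <- tryCatch(final_obj(p_init), error = function(e) -Inf)
  mi_final_full <- tryCatch(final_obj(p), error = function(e) -Inf)
  if (mi_final_full < mi_init_full) {
    p <- p_init
    mi_final_full <- mi_init_full
  }
  if (!is.finite(mi_final_full)) {
    stop("registration diverged: mutual information could not be evaluated ",
         "at any level (no usable overlap)")
  }
  if (all(report$mi_final < report$mi_init - 1e-12)) {
    stop("registration diverged: mutual information decreased across all levels")
  }
  structure(list(
    transform = .affine_from_params(p, center, moving$frame, fixed$frame),
    mi = mi_final_full, mi_init = mi_init_full, params = p,
    center = center, report = report,
    converged = mi_final_full >= mi_init_full),
    class = "affine_registration")
}

#' @export
print.affine_registration <- function(x, ...) {
  cat(sprintf("<affine_registration> %s -> %s, MI %.4f nats (init %.4f)\n",
              x$transform$source, x$transform$target, x$mi, x$mi_init))
  print(x$report, row.names = FALSE)
  invisible(x)
}

# Recover starting parameters from a 4x4 affine and the centre used by the
# parameterization (RShS factorization via QR of the linear block).
.params_from_affine <- function(m, center) {
  A <- m[1:3, 1:3]
  # polar: A = R P with P symmetric positive definite; then P ~ Sh S
  R <- project_so3(A)
  P <- t(R) %*% A
  # upper-triangular factorization of P: P = Sh S with unit-diagonal shear
  S <- diag(P)
  Sh <- P %*% diag(1 / S)
  p <- numeric(12L)
  p[1:3] <- m[1:3, 4] + A %*% center - center
  # Euler xyz angles of R (R = Rx Ry Rz)
  p[5] <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(p[5])) > 1e-9) {
    p[4] <- atan2(-R[2, 3], R[3, 3])
    p[6] <- atan2(-R[1, 2], R[1, 1])
  }
  p[7:9] <- log(pmax(S, 1e-8))
  p[10] <- Sh[1, 2]; p[11] <- Sh[1, 3]; p[12] <- Sh[2, 3]
  p
}

# Run expr with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
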