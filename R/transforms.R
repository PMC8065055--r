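#' @useDynLib trackfuse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif median mad quantile optim setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Tolerances for rigid-ness checking. A rotation block whose orthogonality
# drift is below .rigid_tol is accepted as-is; drift between .rigid_tol and
# .reortho_tol is silently repaired by polar decomposition; larger drift is
# an error.
.rigid_tol <- 1e-9
.reortho_tol <- 1e-6

#' Homogeneous transforms between named coordinate frames
#'
#' A `frame_transform` is a 4x4 homogeneous matrix (millimetre translations)
#' carrying a `source` and a `target` frame name. Rigid transforms have an
#' orthonormal, det = +1 rotation block; affine transforms only require an
#' invertible 3x3 block. Points are column vectors and transforms act by
#' left-multiplication, so `compose(a, b)` means "apply `b`, then `a`" and
#' requires `a$source == b$target`. All frame bookkeeping is checked: chains
#' whose frames do not match head-to-tail are rejected rather than silently
#' multiplied.
#'
#' @param matrix 4x4 numeric matrix, last row `(0, 0, 0, 1)`.
#' @param source,target Frame names (non-empty strings), e.g. `"US"`,
#'   `"trans"`, `"ORF_TABLE"`, `"MR"`, `"TRUS"`.
#' @return An object of class `frame_transform` with elements `matrix`,
#'   `source`, `target` and `rigid` (logical).
#' @examples
#' t1 <- transform_translation(c(10, 0, 0), "A", "B")
#' t2 <- transform_rotation("z", pi / 2, "B", "C")
#' compose(t2, t1)
#' @export
rigid_transform <- function(matrix, source, target) {
  .check_frame(source); .check_frame(target)
  matrix <- .check_homogeneous(matrix)
  R <- matrix[1:3, 1:3]
  drift <- max(abs(crossprod(R) - diag(3)))
  if (drift > .rigid_tol) {
    if (drift > .reortho_tol) {
      stop("rotation block is not orthonormal (drift ", format(drift),
           " exceeds ", format(.reortho_tol), ")")
    }
    R <- project_so3(R)
    matrix[1:3, 1:3] <- R
  }
  if (det(R) < 0) {
    stop("rotation block has det = -1 (reflection); not a rigid transform")
  }
  structure(list(matrix = matrix, source = source, target = target,
                 rigid = TRUE),
            class = "frame_transform")
}

#' @rdname rigid_transform
#' @export
affine_transform <- function(matrix, source, target) {
  .check_frame(source); .check_frame(target)
  matrix <- .check_homogeneous(matrix)
  A <- matrix[1:3, 1:3]
  if (!all(is.finite(A)) || abs(det(A)) < 1e-12 || !is.finite(kappa(A))) {
    stop("affine 3x3 block is singular or ill-conditioned")
  }
  # an affine that happens to be rigid is kept affine unless constructed
  # via rigid_transform(); compose() promotes/demotes as needed
  structure(list(matrix = matrix, source = source, target = target,
                 rigid = FALSE),
            class = "frame_transform")
}

.check_frame <- function(f) {
  if (!is.character(f) || length(f) != 1L || is.na(f) || !nzchar(f)) {
    stop("frame name must be a non-empty string")
  }
  invisible(f)
}

.check_homogeneous <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L))) {
    stop("transform matrix must be numeric 4x4")
  }
  if (!all(is.finite(m))) stop("transform matrix contains non-finite values")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12) {
    stop("last row of a homogeneous transform must be (0, 0, 0, 1)")
  }
  m[4, ] <- c(0, 0, 0, 1)
  dimnames(m) <- NULL
  m
}

#' Project a near-rotation matrix onto SO(3)
#'
#' Polar decomposition via SVD with determinant-sign correction: the closest
#' (Frobenius) proper rotation to `R`.
#'
#' @param R 3x3 numeric matrix.
#' @return 3x3 rotation matrix with `det = +1`.
#' @export
project_so3 <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("<%s transform> %s -> %s\n",
              if (x$rigid) "rigid" else "affine", x$source, x$target))
  print(round(x$matrix, 6))
  invisible(x)
}

is_frame_transform <- function(x) inherits(x, "frame_transform")

#' Identity transform on a frame
#' @param frame Frame name.
#' @param target Optional distinct target frame (defaults to `frame`), for
#'   declaring that two frames coincide.
#' @return A rigid `frame_transform`.
#' @export
transform_identity <- function(frame, target = frame) {
  rigid_transform(diag(4), frame, target)
}

#' Elementary rigid transforms
#'
#' `transform_translation()` builds a pure translation;
#' `transform_rotation()` a rotation about a coordinate axis or arbitrary
#' unit axis through the origin; `transform_rigid()` combines a rotation
#' matrix and translation vector.
#'
#' @param offset Length-3 translation in mm.
#' @param axis `"x"`, `"y"`, `"z"` or a length-3 vector.
#' @param angle Rotation angle in radians.
#' @param R 3x3 rotation matrix.
#' @param source,target Frame names.
#' @return A rigid `frame_transform`.
#' @export
transform_translation <- function(offset, source, target) {
  stopifnot(length(offset) == 3L)
  m <- diag(4)
  m[1:3, 4] <- offset
  rigid_transform(m, source, target)
}

#' @rdname transform_translation
#' @export
transform_rotation <- function(axis, angle, source, target) {
  R <- rotation_matrix(axis, angle)
  m <- diag(4)
  m[1:3, 1:3] <- R
  rigid_transform(m, source, target)
}

#' @rdname transform_translation
#' @export
transform_rigid <- function(R, offset, source, target) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- offset
  rigid_transform(m, source, target)
}

#' Axis-angle rotation matrix (Rodrigues)
#' @param axis `"x"`, `"y"`, `"z"` or length-3 vector (normalized internally).
#' @param angle Radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  stopifnot(length(axis) == 3L)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  a <- axis / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Compose two transforms along matching frames
#'
#' Returns the transform applying `b` first, then `a`; requires
#' `a$source == b$target`. Rigid composed with rigid stays rigid, any other
#' combination is affine.
#'
#' @param a,b `frame_transform` objects.
#' @return A `frame_transform` from `b$source` to `a$target`.
#' @export
compose <- function(a, b) {
  stopifnot(is_frame_transform(a), is_frame_transform(b))
  if (!identical(a$source, b$target)) {
    stop(sprintf(
      "frame chain mismatch: cannot compose %s->%s after %s->%s (need '%s' == '%s')",
      a$source, a$target, b$source, b$target, a$source, b$target))
  }
  m <- a$matrix %*% b$matrix
  out <- list(matrix = m, source = b$source, target = a$target,
              rigid = a$rigid && b$rigid)
  class(out) <- "frame_transform"
  out
}

#' Chain several transforms left to right
#'
#' `compose_chain(a, b, c)` computes `a . b . c` (apply `c` first) with full
#' frame checking at every link.
#' @param ... `frame_transform` objects, leftmost applied last.
#' @return A `frame_transform`.
#' @export
compose_chain <- function(...) {
  links <- list(...)
  if (length(links) == 1L && is.list(links[[1L]]) &&
      !is_frame_transform(links[[1L]])) {
    links <- links[[1L]]
  }
  if (!length(links)) stop("empty transform chain")
  Reduce(compose, links)
}

#' Invert a transform
#'
#' Frames are swapped; for rigid transforms the inverse is formed in closed
#' form from the transposed rotation block.
#' @param t A `frame_transform`.
#' @return The inverse `frame_transform`.
#' @export
invert <- function(t) {
  stopifnot(is_frame_transform(t))
  m <- diag(4)
  if (t$rigid) {
    Rt <- t(t$matrix[1:3, 1:3])
    m[1:3, 1:3] <- Rt
    m[1:3, 4] <- -Rt %*% t$matrix[1:3, 4]
  } else {
    A <- t$matrix[1:3, 1:3]
    Ai <- tryCatch(solve(A), error = function(e) {
      stop("affine transform is singular and cannot be inverted")
    })
    m[1:3, 1:3] <- Ai
    m[1:3, 4] <- -Ai %*% t$matrix[1:3, 4]
  }
  out <- list(matrix = m, source = t$target, target = t$source,
              rigid = t$rigid)
  class(out) <- "frame_transform"
  out
}

#' Apply a transform to points
#'
#' Maps an N x 3 matrix of points (or a length-3 vector, or a
#' [fiducial_set()]) from the transform's source frame to its target frame.
#' When the input carries a frame attribute it is checked against
#' `t$source`.
#'
#' @param t A `frame_transform`.
#' @param p Length-3 vector, N x 3 matrix, or `fiducial_set`.
#' @return Same shape as the input, in the target frame.
#' @export
apply_transform <- function(t, p) {
  stopifnot(is_frame_transform(t))
  if (inherits(p, "fiducial_set")) {
    if (!identical(p$frame, t$source)) {
      stop(sprintf("frame mismatch: points are in '%s' but transform maps '%s' -> '%s'",
                   p$frame, t$source, t$target))
    }
    out <- p
    out$points <- apply_transform(t, p$points)
    out$frame <- t$target
    if (!is.null(p$repeats)) {
      out$repeats <- lapply(p$repeats, function(r) apply_transform(t, r))
    }
    return(out)
  }
  vec <- is.null(dim(p))
  if (vec) {
    stopifnot(length(p) == 3L)
    p <- matrix(p, 1L, 3L)
  }
  stopifnot(ncol(p) == 3L)
  if (!all(is.finite(p))) stop("points contain non-finite coordinates")
  ph <- cbind(p, 1)
  out <- ph %*% t(t$matrix)
  out <- out[, 1:3, drop = FALSE]
  rownames(out) <- rownames(p)
  if (vec) out <- drop(out)
  out
}

#' Are two transforms numerically equal?
#' @param a,b `frame_transform` objects.
#' @param tol Elementwise tolerance.
#' @return Logical.
#' @export
transforms_equal <- function(a, b, tol = 1e-9) {
  identical(a$source, b$source) && identical(a$target, b$target) &&
    max(abs(a$matrix - b$matrix)) <= tol
}

# ---- quaternions (scalar-last, x y z w) --------------------------------

#' Convert between unit quaternions and rotation matrices
#'
#' Quaternions use the scalar-last `(qx, qy, qz, qw)` convention of the pose
#' CSV dialect. `quaternion_to_matrix()` rejects quaternions whose norm
#' deviates from 1 by more than `tol` and renormalizes smaller drift.
#'
#' @param q Length-4 numeric `(qx, qy, qz, qw)`.
#' @param R 3x3 rotation matrix.
#' @param tol Maximum tolerated deviation of the quaternion norm from 1.
#' @return A 3x3 rotation matrix / a length-4 quaternion with `qw >= 0`.
#' @export
quaternion_to_matrix <- function(q, tol = 1e-6) {
  stopifnot(length(q) == 4L, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > tol) {
    stop(sprintf("quaternion norm %.8f deviates from 1 by more than %g", n, tol))
  }
  q <- q / n
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
    2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
    2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' @rdname quaternion_to_matrix
#' @export
matrix_to_quaternion <- function(R) {
  stopifnot(identical(dim(R), c(3L, 3L)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    w <- 0.25 * s
    x <- (R[3, 2] - R[2, 3]) / s
    y <- (R[1, 3] - R[3, 1]) / s
    z <- (R[2, 1] - R[1, 2]) / s
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    w <- (R[3, 2] - R[2, 3]) / s
    x <- 0.25 * s
    y <- (R[1, 2] + R[2, 1]) / s
    z <- (R[1, 3] + R[3, 1]) / s
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    w <- (R[1, 3] - R[3, 1]) / s
    x <- (R[1, 2] + R[2, 1]) / s
    y <- 0.25 * s
    z <- (R[2, 3] + R[3, 2]) / s
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    w <- (R[2, 1] - R[1, 2]) / s
    x <- (R[1, 3] + R[3, 1]) / s
    y <- (R[2, 3] + R[3, 2]) / s
    z <- 0.25 * s
  }
  q <- c(x, y, z, w)
  if (q[4] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# ---- transform text files ----------------------------------------------

#' Read and write 4x4 transform text files
#'
#' The on-disk dialect is a comment header `# source=<frame> target=<frame>`
#' followed by four lines of four whitespace-separated floats (row-major).
#' An optional `kind=affine` token in the header marks non-rigid transforms.
#'
#' @param path File path.
#' @param t A `frame_transform`.
#' @return `read_transform()` returns a `frame_transform`;
#'   `write_transform()` returns `path` invisibly.
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) != 4L) {
    stop("transform file must contain exactly 4 matrix rows: ", path)
  }
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  if (any(vapply(vals, length, 1L) != 4L) || anyNA(unlist(vals))) {
    stop("malformed transform matrix in ", path)
  }
  m <- do.call(rbind, vals)
  get_tok <- function(key) {
    hit <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    hit <- unlist(hit)
    if (!length(hit)) return(NULL)
    sub(paste0(key, "="), "", hit[[1L]])
  }
  source <- get_tok("source"); target <- get_tok("target")
  if (is.null(source) || is.null(target)) {
    stop("transform file header must declare source= and target=: ", path)
  }
  kind <- get_tok("kind")
  if (identical(kind, "affine")) {
    affine_transform(m, source, target)
  } else {
    rigid_transform(m, source, target)
  }
}

#' @rdname read_transform
#' @export
write_transform <- function(t, path) {
  stopifnot(is_frame_transform(t))
  hdr <- sprintf("# source=%s target=%s%s", t$source, t$target,
                 if (t$rigid) "" else " kind=affine")
  rows <- apply(t$matrix, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}
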