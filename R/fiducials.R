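#' Labelled fiducial point sets
#'
#' A `fiducial_set` holds ordered, uniquely labelled 3D points (mm) in one
#' named coordinate frame, optionally with repeated raw readings per label
#' (e.g. a stylus touching each cone tip several times).
#'
#' @param points N x 3 numeric matrix of coordinates in mm.
#' @param frame Frame name the points live in.
#' @param labels Character vector of unique labels; defaults to rownames of
#'   `points` or `"F1"`, `"F2"`, ...
#' @param repeats Optional named list (one entry per label) of k x 3
#'   matrices of raw repeated readings.
#' @return An object of class `fiducial_set`.
#' @examples
#' fs <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 5)), "tank")
#' fs
#' @export
fiducial_set <- function(points, frame, labels = NULL, repeats = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("fiducial points must be N x 3")
  if (!all(is.finite(points))) stop("fiducial coordinates must be finite")
  .check_frame(frame)
  if (is.null(labels)) {
    labels <- rownames(points)
    if (is.null(labels)) labels <- paste0("F", seq_len(nrow(points)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) stop("one label per point required")
  if (anyDuplicated(labels)) stop("fiducial labels must be unique")
  rownames(points) <- labels
  colnames(points) <- c("x", "y", "z")
  if (!is.null(repeats)) {
    if (is.null(names(repeats)) || !all(names(repeats) %in% labels)) {
      stop("repeats must be a named list keyed by point labels")
    }
    repeats <- lapply(repeats, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 3L || nrow(r) < 1L || !all(is.finite(r))) {
        stop("each repeats entry must be a non-empty k x 3 finite matrix")
      }
      colnames(r) <- c("x", "y", "z")
      r
    })
  }
  structure(list(points = points, frame = frame, labels = labels,
                 repeats = repeats),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d points in frame '%s'%s\n",
              nrow(x$points), x$frame,
              if (is.null(x$repeats)) "" else
                sprintf(" (repeats: %s readings/label)",
                        paste(range(vapply(x$repeats, nrow, 1L)),
                              collapse = "-"))))
  print(round(x$points, 4))
  invisible(x)
}

#' @export
as.data.frame.fiducial_set <- function(x, ...) {
  data.frame(label = x$labels, x = x$points[, 1], y = x$points[, 2],
             z = x$points[, 3], row.names = NULL)
}

#' @export
length.fiducial_set <- function(x) nrow(x$points)

#' Subset a fiducial set by labels
#' @param fs A `fiducial_set`.
#' @param labels Labels to keep, in the order given.
#' @return A `fiducial_set`.
#' @export
subset_fiducials <- function(fs, labels) {
  stopifnot(inherits(fs, "fiducial_set"))
  missing <- setdiff(labels, fs$labels)
  if (length(missing)) {
    stop("labels not present in fiducial set: ", paste(missing, collapse = ", "))
  }
  fiducial_set(fs$points[labels, , drop = FALSE], fs$frame, labels,
               repeats = if (!is.null(fs$repeats))
                 fs$repeats[intersect(names(fs$repeats), labels)])
}

#' Average repeated fiducial readings
#'
#' Collapses per-label repeated raw readings (e.g. 10 stylus touches per
#' cone tip) to one point per label: a reading whose distance to the
#' per-label median point exceeds the median of those distances by more than
#' `mad_k` scaled median absolute deviations is discarded as an outlier, the
#' rest are averaged arithmetically. The per-label spread
#' (RMS distance of the retained readings about their mean) is returned as
#' a jitter estimate; for isotropic per-axis noise of SD sigma and k
#' readings its expectation is `sigma * sqrt(3) * sqrt((k - 1) / k)`.
#'
#' @param raw A `fiducial_set` with a `repeats` list (labels without repeats
#'   keep their stored point and get spread 0).
#' @param mad_k Outlier cut in scaled-MAD units (default 5; with only
#'   ~10 readings per label the MAD estimate is noisy, and a tighter cut
#'   trims enough clean readings to bias the spread estimate low).
#' @return A `fiducial_set` (no repeats) with attributes `spread_mm` (named
#'   per-label RMS spread), `n_used` and `n_rejected`.
#' @export
average_repeats <- function(raw, mad_k = 5) {
  stopifnot(inherits(raw, "fiducial_set"))
  if (is.null(raw$repeats)) {
    out <- fiducial_set(raw$points, raw$frame, raw$labels)
    attr(out, "spread_mm") <- setNames(numeric(length(raw$labels)), raw$labels)
    attr(out, "n_used") <- setNames(rep(1L, length(raw$labels)), raw$labels)
    attr(out, "n_rejected") <- setNames(rep(0L, length(raw$labels)), raw$labels)
    return(out)
  }
  pts <- raw$points
  spread <- n_used <- n_rej <- setNames(numeric(nrow(pts)), raw$labels)
  for (lab in raw$labels) {
    r <- raw$repeats[[lab]]
    if (is.null(r)) {
      r <- raw$points[lab, , drop = FALSE]
    }
    if (nrow(r) == 0L) stop("label '", lab, "' has zero readings")
    keep <- rep(TRUE, nrow(r))
    if (nrow(r) >= 3L) {
      med <- apply(r, 2L, median)
      dev <- sqrt(rowSums(sweep(r, 2L, med)^2))
      # distances are non-negative, so the cut is centred on their median
      keep <- dev <= median(dev) + mad_k * mad(dev)
      if (!any(keep)) keep <- dev == min(dev)  # never discard everything
    }
    rk <- r[keep, , drop = FALSE]
    m <- colMeans(rk)
    pts[lab, ] <- m
    spread[lab] <- sqrt(mean(rowSums(sweep(rk, 2L, m)^2)))
    n_used[lab] <- nrow(rk)
    n_rej[lab] <- nrow(r) - nrow(rk)
  }
  out <- fiducial_set(pts, raw$frame, raw$labels)
  attr(out, "spread_mm") <- spread
  attr(out, "n_used") <- n_used
  attr(out, "n_rejected") <- n_rej
  out
}
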