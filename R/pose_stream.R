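#' Tracker pose streams
#'
#' A `pose_stream` is an ordered set of timestamped optical-tracker
#' readings, each a rigid pose of a named tool in the tracker frame, with a
#' validity flag (tools can drop out of the camera's line of sight).
#' Internally it is a data frame with columns `time_s`, `tool_id`, `tx`,
#' `ty`, `tz` (mm), `qx`, `qy`, `qz`, `qw` (unit quaternion, scalar-last)
#' and `valid`.
#'
#' @param time_s Numeric, non-decreasing acquisition times (s).
#' @param tool_id Character tool identifiers.
#' @param translations N x 3 matrix of tool origins in tracker mm.
#' @param quaternions N x 4 matrix, scalar-last `(qx, qy, qz, qw)`.
#' @param valid Logical vector (default all `TRUE`).
#' @param tracker_frame Name of the tracker frame (default `"tracker"`).
#' @return An object of class `pose_stream` (also a data frame).
#' @export
pose_stream <- function(time_s, tool_id, translations, quaternions,
                        valid = TRUE, tracker_frame = "tracker") {
  translations <- as.matrix(translations)
  quaternions <- as.matrix(quaternions)
  n <- length(time_s)
  stopifnot(nrow(translations) == n, ncol(translations) == 3L,
            nrow(quaternions) == n, ncol(quaternions) == 4L,
            length(tool_id) == n)
  if (is.unsorted(time_s)) stop("pose times must be non-decreasing")
  valid <- rep_len(as.logical(valid), n)
  qn <- sqrt(rowSums(quaternions^2))
  bad <- which(valid & abs(qn - 1) > 1e-6)
  if (length(bad)) {
    stop("non-unit quaternion(s) at reading(s) ",
         paste(head(bad, 5L), collapse = ", "),
         " (norm deviates from 1 by more than 1e-6)")
  }
  quaternions <- quaternions / qn
  df <- data.frame(time_s = as.numeric(time_s),
                   tool_id = as.character(tool_id),
                   tx = translations[, 1], ty = translations[, 2],
                   tz = translations[, 3],
                   qx = quaternions[, 1], qy = quaternions[, 2],
                   qz = quaternions[, 3], qw = quaternions[, 4],
                   valid = valid)
  attr(df, "tracker_frame") <- tracker_frame
  class(df) <- c("pose_stream", "data.frame")
  df
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream> %d readings, tools: %s, frame '%s'\n",
              nrow(x), paste(unique(x$tool_id), collapse = ", "),
              attr(x, "tracker_frame")))
  print.data.frame(head(as.data.frame(x), 6L), digits = 5)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more readings\n")
  invisible(x)
}

#' Extract one reading as a rigid transform
#' @param stream A `pose_stream`.
#' @param i Row index.
#' @return A rigid `frame_transform` tool -> tracker.
#' @export
pose_at <- function(stream, i) {
  stopifnot(inherits(stream, "pose_stream"))
  row <- stream[i, ]
  R <- quaternion_to_matrix(c(row$qx, row$qy, row$qz, row$qw))
  transform_rigid(R, c(row$tx, row$ty, row$tz),
                  source = row$tool_id,
                  target = attr(stream, "tracker_frame"))
}

#' Keep only readings of one tool
#' @param stream A `pose_stream`.
#' @param tool_id Tool identifier.
#' @param valid_only Drop invalid readings (default `TRUE`).
#' @return A `pose_stream`.
#' @export
filter_tool <- function(stream, tool_id, valid_only = TRUE) {
  stopifnot(inherits(stream, "pose_stream"))
  keep <- stream$tool_id == tool_id & (!valid_only | stream$valid)
  out <- stream[keep, , drop = FALSE]
  attr(out, "tracker_frame") <- attr(stream, "tracker_frame")
  class(out) <- c("pose_stream", "data.frame")
  out
}

#' Average an epoch of poses of one tool
#'
#' Jitter suppression for a statically held tool: the translation is the
#' arithmetic mean and the rotation is the chordal mean (the averaged
#' rotation matrix projected back onto SO(3)), which is adequate for the
#' sub-degree jitter of an optical tracker.
#'
#' @param stream A `pose_stream`.
#' @param tool_id Tool to average; default the only tool present.
#' @return A rigid `frame_transform` tool -> tracker, with attribute
#'   `n_readings`.
#' @export
average_pose <- function(stream, tool_id = NULL) {
  stopifnot(inherits(stream, "pose_stream"))
  if (is.null(tool_id)) {
    ids <- unique(stream$tool_id)
    if (length(ids) != 1L) {
      stop("stream contains several tools; specify tool_id")
    }
    tool_id <- ids
  }
  s <- filter_tool(stream, tool_id)
  if (nrow(s) == 0L) {
    stop("no valid readings for tool '", tool_id, "'")
  }
  Rsum <- matrix(0, 3, 3)
  for (i in seq_len(nrow(s))) {
    Rsum <- Rsum + quaternion_to_matrix(c(s$qx[i], s$qy[i], s$qz[i], s$qw[i]))
  }
  R <- project_so3(Rsum / nrow(s))
  out <- transform_rigid(R, c(mean(s$tx), mean(s$ty), mean(s$tz)),
                         source = tool_id,
                         target = attr(s, "tracker_frame"))
  attr(out, "n_readings") <- nrow(s)
  out
}

#' Read and write tracker pose CSV files
#'
#' Dialect: header `time_s,tool_id,tx,ty,tz,qx,qy,qz,qw,valid`, mm
#' translations, scalar-last unit quaternions. Valid readings whose
#' quaternion norm deviates from 1 by more than 1e-6 are rejected.
#'
#' @param path File path.
#' @param stream A `pose_stream`.
#' @param tracker_frame Frame name to attach on read.
#' @return `read_poses()` returns a `pose_stream`; `write_poses()` returns
#'   `path` invisibly.
#' @export
read_poses <- function(path, tracker_frame = "tracker") {
  if (!file.exists(path)) stop("pose file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "tool_id", "tx", "ty", "tz", "qx", "qy", "qz", "qw",
            "valid")
  if (!all(need %in% names(df))) {
    stop("pose CSV must have columns ", paste(need, collapse = ","),
         ": ", path)
  }
  pose_stream(df$time_s, df$tool_id,
              cbind(df$tx, df$ty, df$tz),
              cbind(df$qx, df$qy, df$qz, df$qw),
              valid = as.logical(df$valid),
              tracker_frame = tracker_frame)
}

#' @rdname read_poses
#' @export
write_poses <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  write.csv(as.data.frame(stream), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
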