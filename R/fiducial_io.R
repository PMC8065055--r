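#' Read and write fiducial files (FCSV, markups JSON, plain CSV)
#'
#' Supported dialects, chosen by extension:
#' * `.fcsv` - 3D Slicer fiducial CSV. Slicer writes RAS coordinates; they
#'   are converted to the internal LPS convention on read (`x, y -> -x,
#'   -y`) and back on write, regardless of header hints.
#' * `.json` / `.mrk.json` - Slicer markups JSON; the declared
#'   `coordinateSystem` field (`"LPS"` or `"RAS"`) is honoured.
#' * `.csv` - plain `label,x,y,z` in mm, no axis convention applied.
#'
#' @param path File path.
#' @param fs A `fiducial_set`.
#' @param frame Frame name to attach on read (default `"world"`).
#' @return `read_fiducials()` returns a `fiducial_set`;
#'   `write_fiducials()` returns `path` invisibly.
#' @export
read_fiducials <- function(path, frame = "world") {
  if (!file.exists(path)) stop("fiducial file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.fcsv$", lower)) {
    .read_fcsv(path, frame)
  } else if (grepl("\\.json$", lower)) {
    .read_markups_json(path, frame)
  } else if (grepl("\\.csv$", lower)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("plain fiducial CSV needs columns label,x,y,z: ", path)
    }
    if (anyDuplicated(df$label)) stop("duplicate fiducial labels in ", path)
    fiducial_set(cbind(df$x, df$y, df$z), frame, labels = df$label)
  } else {
    stop("unsupported fiducial format (need .fcsv, .json or .csv): ", path)
  }
}

#' @rdname read_fiducials
#' @export
write_fiducials <- function(fs, path) {
  stopifnot(inherits(fs, "fiducial_set"))
  lower <- tolower(path)
  if (grepl("\\.fcsv$", lower)) {
    .write_fcsv(fs, path)
  } else if (grepl("\\.json$", lower)) {
    .write_markups_json(fs, path)
  } else if (grepl("\\.csv$", lower)) {
    # full-precision coordinates so the round trip is bitwise
    rows <- sprintf("%s,%.17g,%.17g,%.17g", fs$labels,
                    fs$points[, 1], fs$points[, 2], fs$points[, 3])
    writeLines(c("label,x,y,z", rows), path)
  } else {
    stop("unsupported fiducial format (need .fcsv, .json or .csv): ", path)
  }
  invisible(path)
}

.read_fcsv <- function(path, frame) {
  lines <- readLines(path, warn = FALSE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("FCSV file has no fiducial rows: ", path)
  fields <- strsplit(body, ",")
  pts <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3L)))
  labels <- vapply(fields, function(f) {
    if (length(f) >= 12L && nzchar(f[12L])) f[12L] else f[1L]
  }, "")
  if (anyNA(pts)) stop("malformed FCSV coordinates in ", path)
  if (anyDuplicated(labels)) stop("duplicate fiducial labels in ", path)
  # Slicer FCSV is RAS; convert to LPS
  pts[, 1] <- -pts[, 1]
  pts[, 2] <- -pts[, 2]
  fiducial_set(pts, frame, labels = labels)
}

.write_fcsv <- function(fs, path) {
  hdr <- c("# Markups fiducial file version = 4.11",
           "# CoordinateSystem = RAS",
           "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  pts <- fs$points
  rows <- vapply(seq_len(nrow(pts)), function(i) {
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%.10g,%.10g,%.10g,0,0,0,1,1,1,0,%s,,",
            i, -pts[i, 1], -pts[i, 2], pts[i, 3], fs$labels[i])
  }, "")
  writeLines(c(hdr, rows), path)
}

.read_markups_json <- function(path, frame) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  markups <- doc$markups
  if (is.null(markups) || !length(markups)) {
    stop("no markups found in ", path)
  }
  mk <- markups[[1L]]
  cs <- toupper(mk$coordinateSystem %||% "LPS")
  cps <- mk$controlPoints
  if (is.null(cps) || !length(cps)) stop("no control points in ", path)
  pts <- t(vapply(cps, function(cp) as.numeric(unlist(cp$position)),
                  numeric(3L)))
  labels <- vapply(seq_along(cps), function(i) {
    lab <- cps[[i]]$label
    if (is.null(lab) || !nzchar(lab)) paste0("F", i) else lab
  }, "")
  if (anyDuplicated(labels)) stop("duplicate fiducial labels in ", path)
  if (cs == "RAS") {
    pts[, 1] <- -pts[, 1]
    pts[, 2] <- -pts[, 2]
  } else if (cs != "LPS") {
    stop("unsupported coordinateSystem '", cs, "' in ", path)
  }
  fiducial_set(pts, frame, labels = labels)
}

.write_markups_json <- function(fs, path) {
  cps <- lapply(seq_len(nrow(fs$points)), function(i) {
    list(id = as.character(i), label = fs$labels[i],
         position = as.numeric(fs$points[i, ]))
  })
  doc <- list(
    `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json",
    markups = list(list(type = "Fiducial", coordinateSystem = "LPS",
                        controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
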