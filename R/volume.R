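#' Regular 3D image volumes and label masks
#'
#' A `volume_image` is a 3D voxel array with geometric metadata: `spacing`
#' (mm, per axis), `origin` (world mm of the centre of voxel `(0,0,0)`),
#' `direction` (3x3 orthonormal matrix whose columns are the world
#' directions of the voxel axes) and a named coordinate `frame`. World
#' coordinates follow the LPS anatomical convention internally; RAS-coded
#' files are converted at I/O. A `label_mask` is a `volume_image` whose
#' voxels are 0/1.
#'
#' @param voxels 3D numeric (or logical) array.
#' @param spacing Length-3 positive voxel size in mm.
#' @param origin Length-3 world position of voxel `(0,0,0)` centre, mm.
#' @param direction 3x3 orthonormal direction matrix (default identity).
#' @param frame Coordinate frame name (default `"world"`).
#' @return An object of class `volume_image` (for `label_mask`, classes
#'   `c("label_mask", "volume_image")` with logical storage coerced to
#'   0/1).
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3), frame = "world") {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive")
  }
  direction <- as.matrix(direction)
  stopifnot(identical(dim(direction), c(3L, 3L)))
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6) {
    stop("direction matrix must be orthonormal")
  }
  .check_frame(frame)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction, frame = frame),
            class = "volume_image")
}

#' @rdname volume_image
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3), frame = "world") {
  voxels <- array(as.numeric(voxels != 0), dim = dim(voxels))
  v <- volume_image(voxels, spacing, origin, direction, frame)
  class(v) <- c("label_mask", "volume_image")
  v
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %dx%dx%d voxels, spacing %s mm, frame '%s'\n",
              class(x)[1L], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"), x$frame))
  rng <- range(x$voxels)
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "), rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

is_volume <- function(x) inherits(x, "volume_image")

#' Voxel-grid geometry helpers
#'
#' `voxel_to_world()` maps 0-based continuous voxel indices to world mm
#' (`origin + direction %*% (spacing * index)`); `world_to_voxel()` is its
#' inverse. `same_grid()` tests whether two volumes share a voxel grid
#' within tolerance.
#'
#' @param v A `volume_image`.
#' @param idx N x 3 matrix of 0-based voxel indices (may be fractional).
#' @param xyz N x 3 matrix of world coordinates in mm.
#' @param a,b `volume_image` objects.
#' @param tol Metadata tolerance for `same_grid()`.
#' @return N x 3 coordinate matrix / logical.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- if (is.null(dim(idx))) matrix(idx, 1L) else as.matrix(idx)
  scaled <- sweep(idx, 2L, v$spacing, `*`)
  sweep(scaled %*% t(v$direction), 2L, v$origin, `+`)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, 1L) else as.matrix(xyz)
  local <- sweep(xyz, 2L, v$origin) %*% v$direction
  sweep(local, 2L, v$spacing, `/`)
}

#' @rdname voxel_to_world
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' World coordinates of all voxel centres
#' @param v A `volume_image`.
#' @return N x 3 matrix (N = number of voxels, fastest index first).
#' @export
voxel_centers <- function(v) {
  d <- dim(v$voxels)
  idx <- cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  voxel_to_world(v, idx)
}

# ---- NIfTI I/O ----------------------------------------------------------

# RAS <-> LPS: flip the sign of the first two world axes
.ras_lps_flip <- diag(c(-1, -1, 1))

#' Read and write 3D volumes (NIfTI-1, MetaImage)
#'
#' Formats are chosen by extension: `.nii`/`.nii.gz` (NIfTI-1, via RNifti)
#' or `.mha`/`.mhd` (MetaImage). NIfTI stores its affine in RAS; it is
#' converted to the internal LPS convention on read and back on write.
#' MetaImage is already LPS. Spacing, origin and direction are preserved to
#' at least 1e-6; voxels round-trip bitwise for double data.
#'
#' @param path File path.
#' @param v A `volume_image`.
#' @param frame Frame name to attach on read (default `"world"`).
#' @return `read_volume()` returns a `volume_image`; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, frame = "world") {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    .read_nifti(path, frame)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    .read_metaimage(path, frame)
  } else {
    stop("unsupported volume format (need .nii, .nii.gz, .mha or .mhd): ",
         path)
  }
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume(v))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    .write_nifti(v, path)
  } else if (grepl("\\.(mha|mhd)$", lower)) {
    .write_metaimage(v, path)
  } else {
    stop("unsupported volume format (need .nii, .nii.gz, .mha or .mhd): ",
         path)
  }
  invisible(path)
}

.read_nifti <- function(path, frame) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI file ",
                                           path, ": ", conditionMessage(e)))
  vox <- as.array(img)
  if (length(dim(vox)) == 4L && dim(vox)[4] == 1L) {
    vox <- array(vox, dim = dim(vox)[1:3])
  }
  if (length(dim(vox)) != 3L) stop("only 3D NIfTI volumes are supported: ", path)
  aff_ras <- structure(RNifti::xform(img), code = NULL)   # voxel -> RAS mm
  aff <- .ras_lps_flip %*% aff_ras[1:3, ]                  # voxel -> LPS mm
  A <- aff[, 1:3]
  spacing <- sqrt(colSums(A^2))
  direction <- sweep(A, 2L, spacing, `/`)
  # repair sub-1e-6 numerical drift from the quaternion representation
  direction <- project_so3(direction) |> zapsmall(digits = 12)
  volume_image(vox, spacing = spacing, origin = aff[, 4],
               direction = direction, frame = frame)
}

.write_nifti <- function(v, path) {
  A <- v$direction %*% diag(v$spacing)
  aff_lps <- cbind(A, v$origin)
  aff_ras <- rbind(.ras_lps_flip %*% aff_lps, c(0, 0, 0, 1))
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(aff_ras, code = 2L)
  RNifti::qform(img) <- structure(aff_ras, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# ---- MetaImage I/O ------------------------------------------------------
# Minimal MetaImage implementation (no installed R package reads .mha/.mhd):
# uncompressed binary little-endian, LOCAL (.mha) or .raw companion (.mhd).

.met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
.met_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                MET_FLOAT = 4L, MET_DOUBLE = 8L)

.read_metaimage <- function(path, frame) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  data_offset <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed MetaImage header line in ", path,
                              ": ", line)
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L) stop("only 3D MetaImage volumes are supported: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1L]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                                "\\s+")[[1L]])
  direction <- if (!is.null(hdr$TransformMatrix)) {
    # MetaImage stores the direction cosines row-major
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1L]]), 3L, 3L,
           byrow = TRUE)
  } else diag(3)
  type <- hdr$ElementType %||% "MET_DOUBLE"
  if (!type %in% names(.met_types)) {
    stop("unsupported MetaImage ElementType '", type, "' in ", path)
  }
  if (!is.null(hdr$CompressedData) &&
      toupper(hdr$CompressedData) == "TRUE") {
    stop("compressed MetaImage data is not supported: ", path)
  }
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) {
      stop("MetaImage data file not found: ", raw_path)
    }
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  what <- .met_types[[type]]
  size <- .met_sizes[[type]]
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(raw_con, what = what, n = n, size = size,
                  signed = if (size < 4L) signed else TRUE,
                  endian = "little")
  if (length(vals) != n) stop("truncated MetaImage voxel data: ", path)
  volume_image(array(as.numeric(vals), dim = dims), spacing = spacing,
               origin = origin, direction = direction, frame = frame)
}

.write_metaimage <- function(v, path) {
  local <- grepl("\\.mha$", tolower(path))
  datafile <- if (local) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(sprintf("%.17g", t(v$direction)), collapse = " ")),
    paste("Offset =", paste(sprintf("%.17g", v$origin), collapse = " ")),
    paste("ElementSpacing =", paste(sprintf("%.17g", v$spacing), collapse = " ")),
    paste("DimSize =", paste(dim(v$voxels), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local) {
    writeBin(as.numeric(v$voxels), con, size = 8L, endian = "little")
  } else {
    raw_con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(raw_con), add = TRUE)
    writeBin(as.numeric(v$voxels), raw_con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
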