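## Label-volume container and file I/O.
##
## Coordinate contract used by every other module:
##   * voxel indices are 0-based and address voxel CENTERS;
##   * world coordinate of voxel (i,j,k) = origin + (i,j,k) * spacing, in mm;
##   * voxel values: 0 background, 1 condyle, 2 fossa.

LABEL_BACKGROUND <- 0L
LABEL_CONDYLE    <- 1L
LABEL_FOSSA      <- 2L

#' Construct a label volume
#'
#' A `label_volume` holds a 3D integer grid of segmentation labels
#' (0 = background, 1 = condyle, 2 = fossa) together with its physical
#' geometry: per-axis voxel size in mm and the world position of the center
#' of voxel (0,0,0).  Voxel indices are 0-based and address voxel centers,
#' so the world coordinate of voxel (i,j,k) is `origin + c(i,j,k) * spacing`.
#'
#' @param voxels 3D integer array with values in \{0, 1, 2\}.
#' @param spacing numeric length-3, per-axis voxel size in mm; all > 0.
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel (0,0,0).
#' @param superior_axis which array axis points superior (toward the fossa);
#'   defaults to the third axis, matching scanner-aligned exports.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         superior_axis = 3L) {
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  if (!is.integer(voxels)) {
    if (any(voxels != round(voxels)))
      stop("'voxels' must hold integer labels")
    storage.mode(voxels) <- "integer"
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  superior_axis <- as.integer(superior_axis)
  if (!superior_axis %in% 1:3)
    stop("'superior_axis' must be 1, 2 or 3")
  bad <- setdiff(unique(as.vector(voxels)),
                 c(LABEL_BACKGROUND, LABEL_CONDYLE, LABEL_FOSSA))
  if (length(bad))
    stop("invalid voxel label value(s): ", paste(sort(bad), collapse = ", "),
         " (allowed: 0, 1, 2)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 superior_axis = superior_axis),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, superior axis %d\n",
              x$origin[1], x$origin[2], x$origin[3], x$superior_axis))
  cat(sprintf("  condyle voxels: %d, fossa voxels: %d\n",
              sum(x$voxels == LABEL_CONDYLE), sum(x$voxels == LABEL_FOSSA)))
  invisible(x)
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param volume a [label_volume].
#' @param index numeric vector of length 3 or an n x 3 matrix of 0-based
#'   voxel indices (may be fractional).
#' @return World coordinates, same shape as `index`.
#' @export
voxel_to_world <- function(volume, index) {
  if (is.matrix(index))
    sweep(sweep(index, 2L, volume$spacing, `*`), 2L, volume$origin, `+`)
  else
    volume$origin + index * volume$spacing
}

#' Map world coordinates (mm) to fractional 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param point numeric length 3 or an n x 3 matrix of world points (mm).
#' @export
world_to_voxel <- function(volume, point) {
  if (is.matrix(point))
    sweep(sweep(point, 2L, volume$origin, `-`), 2L, volume$spacing, `/`)
  else
    (point - volume$origin) / volume$spacing
}

## ---- file formats ---------------------------------------------------------

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else if (grepl("\\.mha$", lower) || grepl("\\.mhd$", lower)) "metaimage"
  else if (grepl("\\.nrrd$", lower))
    stop("NRRD volumes are not supported; convert to NIfTI (.nii/.nii.gz) ",
         "or MetaImage (.mha)")
  else stop("unrecognized volume format: ", path,
            " (expected .nii, .nii.gz, .mha or .mhd)")
}

#' Read a condyle/fossa label volume from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`).
#' Spacing and origin are taken from the file header; voxel values are
#' validated against the label alphabet \{0, 1, 2\}.
#'
#' @param path path to the volume file.
#' @param superior_axis array axis pointing superior; default 3.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path, superior_axis = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    vox <- as.array(img)
    if (length(dim(vox)) != 3L) stop("expected a 3D volume: ", path)
    if (any(vox != round(vox)))
      stop("non-integer voxel values in ", path)
    vox <- array(as.integer(vox), dim = dim(vox))
    xf <- RNifti::xform(img)
    spacing <- abs(RNifti::pixdim(img))[1:3]
    origin <- xf[1:3, 4]
    label_volume(vox, spacing = spacing, origin = origin,
                 superior_axis = superior_axis)
  } else {
    read_metaimage(path, superior_axis = superior_axis)
  }
}

#' Write a label volume to disk
#'
#' MetaImage (`.mha`) stores spacing and origin as full-precision text and
#' round-trips doubles exactly; NIfTI headers hold them as 32-bit floats.
#'
#' @param volume a [label_volume].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(volume$voxels)
    m <- diag(4)
    diag(m)[1:3] <- volume$spacing
    m[1:3, 4] <- volume$origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    if (grepl("\\.mhd$", tolower(path)))
      stop("writing uses single-file .mha (header + LOCAL data); got .mhd")
    write_metaimage(volume, path)
  }
  invisible(path)
}

## MetaImage: ASCII "Key = value" header followed by a raw little-endian
## block when ElementDataFile = LOCAL.  Minimal reader/writer for the label
## volumes this package exchanges.

write_metaimage <- function(volume, path) {
  d <- dim(volume$voxels)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    "ElementType = MET_INT",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(volume$voxels), con, size = 4L, endian = "little")
  invisible(path)
}

read_metaimage <- function(path, superior_axis = 3L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected NDims = 3 MetaImage: ", path)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_INT"
  size <- switch(type, MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                 MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                 stop("unsupported MetaImage ElementType: ", type))
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT")
  endian <- if (identical(hdr$BinaryDataByteOrderMSB, "True") ||
                identical(hdr$ElementByteOrderMSB, "True")) "big" else "little"
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, "integer", n = n, size = size,
                   signed = signed, endian = endian)
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, "integer", n = n, size = size,
                   signed = signed, endian = endian)
  }
  if (length(raw) != n) stop("truncated MetaImage data block: ", path)
  label_volume(array(raw, dim = dims), spacing = spacing, origin = origin,
               superior_axis = superior_axis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- feature tables -------------------------------------------------------

#' Write per-joint ray features to CSV
#'
#' The table has one row per joint and columns `joint_id`, `label`,
#' `ray_000..ray_{N-1}` (gap distances, mm) and `imputed_000..imputed_{N-1}`
#' (0/1 flags for rays whose gap was imputed).  Values are written with
#' enough digits to round-trip doubles exactly.
#'
#' @param features a list of [ray_features] objects (equal length N).
#' @param path output CSV path.
#' @param labels optional character vector of labels ("correct"/"incorrect"),
#'   recycled from the features' `label` fields when absent.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, labels = NULL) {
  if (!length(features)) stop("no feature vectors to write")
  lens <- vapply(features, function(f) length(f$distances), integer(1))
  if (length(unique(lens)) != 1L)
    stop("ragged feature vectors: lengths ", paste(unique(lens), collapse = ", "))
  n <- lens[1]
  if (is.null(labels))
    labels <- vapply(features, function(f) f$label %||% NA_character_,
                     character(1))
  idx <- formatC(seq_len(n) - 1L, width = 3, flag = "0")
  mat <- do.call(rbind, lapply(features, function(f) f$distances))
  imp <- do.call(rbind, lapply(features, function(f) as.integer(f$imputed)))
  dt <- data.table::data.table(
    joint_id = vapply(features, function(f) f$joint_id, character(1)),
    label = labels)
  # %.17g text guarantees the doubles survive the round-trip exactly
  mat_chr <- `colnames<-`(array(sprintf("%.17g", mat), dim = dim(mat)),
                          paste0("ray_", idx))
  dt <- cbind(dt,
              data.table::as.data.table(mat_chr),
              data.table::as.data.table(`colnames<-`(imp, paste0("imputed_", idx))))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a ray-feature CSV written by [write_features]
#'
#' @param path CSV path.
#' @return A list with `joint_id`, `label`, `distances` (matrix, joints x N)
#'   and `imputed` (logical matrix).
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path)
  ray_cols <- grep("^ray_", names(dt), value = TRUE)
  imp_cols <- grep("^imputed_", names(dt), value = TRUE)
  list(joint_id = dt$joint_id,
       label = dt$label,
       distances = as.matrix(dt[, ray_cols, with = FALSE]),
       imputed = as.matrix(dt[, imp_cols, with = FALSE]) > 0)
}
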