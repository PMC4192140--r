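#' Construct a GreyVolume
#'
#' @param data 3D numeric array (axis 1 = coronal slice AP, axis 2 =
#'   proximal to distal, axis 3 = medial to lateral).
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @param intensityUnits `"raw"` or `"HU"`.
#' @return a [GreyVolume-class].
#' @export
greyVolume <- function(data, voxelSizeUm, intensityUnits = "raw") {
  new("GreyVolume", data = data, voxelSizeUm = as.numeric(voxelSizeUm),
      intensityUnits = intensityUnits)
}

#' Construct a VoxelMask
#'
#' @param data 3D logical array in the package axes convention.
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @param label compartment label.
#' @return a [VoxelMask-class].
#' @export
voxelMask <- function(data, voxelSizeUm, label = "") {
  storage.mode(data) <- "logical"
  new("VoxelMask", data = data, voxelSizeUm = as.numeric(voxelSizeUm),
      label = label)
}

#' Construct a two-point Hounsfield calibration
#'
#' @param meanWaterEquivalent mean raw intensity of the immersion-fluid
#'   (water-equivalent) reference region.
#' @param meanAir mean raw intensity of an air/background reference region.
#' @return an [HUCalibration-class].
#' @export
huCalibration <- function(meanWaterEquivalent, meanAir) {
  new("HUCalibration", meanWaterEquivalent = as.numeric(meanWaterEquivalent),
      meanAir = as.numeric(meanAir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- TIFF helpers -------------------------------------------------------

readTiffSlice <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  fmt <- attr(x, "sample.format") %||% "uint"
  if (identical(fmt, "float")) x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]   # drop extra channels
  x
}

readTiffStack <- function(paths) {
  slices <- lapply(paths, readTiffSlice)
  d <- dim(slices[[1L]])
  for (s in slices)
    if (!identical(dim(s), d))
      stop("inconsistent slice dimensions in TIFF stack")
  out <- array(0, c(length(slices), d[1L], d[2L]))
  for (i in seq_along(slices)) out[i, , ] <- slices[[i]]
  out
}

## ---- NRRD ---------------------------------------------------------------

nrrdTypes <- list(
  uchar = list(what = "integer", size = 1L, signed = FALSE),
  short = list(what = "integer", size = 2L, signed = TRUE),
  ushort = list(what = "integer", size = 2L, signed = FALSE),
  int = list(what = "integer", size = 4L, signed = TRUE),
  float = list(what = "double", size = 4L, signed = TRUE),
  double = list(what = "double", size = 8L, signed = TRUE))

normalizeNrrdType <- function(ty) {
  switch(ty,
    "unsigned char" = , "uint8" = , "uint8_t" = "uchar",
    "signed short" = , "short int" = , "int16" = , "int16_t" = "short",
    "unsigned short" = , "uint16" = , "uint16_t" = "ushort",
    "signed int" = , "int32" = , "int32_t" = "int",
    ty)
}

readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1L]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2L]))]] <- trimws(kv[3L])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1L]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  ty <- normalizeNrrdType(fields[["type"]])
  info <- nrrdTypes[[ty]]
  if (is.null(info)) stop("unsupported NRRD type: ", fields[["type"]])
  enc <- fields[["encoding"]] %||% "raw"
  n <- prod(sizes)
  if (enc == "raw") {
    vals <- readBin(con, info$what, n = n, size = info$size,
                    signed = info$signed, endian = "little")
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.info(path)$size)
    vals <- readBin(memDecompress(comp, type = "gzip"), info$what, n = n,
                    size = info$size, signed = info$signed,
                    endian = "little")
  } else stop("unsupported NRRD encoding: ", enc)
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
    spacing <- sp[is.finite(sp)]
  }
  list(data = array(vals, sizes), spacing = spacing)
}

writeNrrd <- function(data, path, spacingUm) {
  ty <- if (is.integer(data) ||
            (is.numeric(data) && all(data == round(data)) &&
             max(abs(data)) <= .Machine$integer.max)) "int" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", ty),
           "dimension: 3",
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(rep(spacingUm, 3L), collapse = " ")),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con)
  if (ty == "int") {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

## ---- MHD/RAW ------------------------------------------------------------

mhdTypes <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "double", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE))

readMhd <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) >= 2L)
      kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
  }
  sizes <- as.integer(strsplit(kv[["DimSize"]], "\\s+")[[1L]])
  if (length(sizes) != 3L) stop("only 3D MHD volumes are supported")
  info <- mhdTypes[[kv[["ElementType"]]]]
  if (is.null(info)) stop("unsupported MHD ElementType: ", kv[["ElementType"]])
  rawPath <- file.path(dirname(path), kv[["ElementDataFile"]])
  con <- file(rawPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, info$what, n = prod(sizes), size = info$size,
                  signed = info$signed, endian = "little")
  spacing <- NULL
  if (!is.null(kv[["ElementSpacing"]]))
    spacing <- as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1L]])
  list(data = array(vals, sizes), spacing = spacing)
}

writeMhd <- function(data, path, spacingUm) {
  rawName <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  isInt <- is.integer(data) ||
    (is.numeric(data) && all(data == round(data)) &&
     max(abs(data)) <= .Machine$integer.max)
  ty <- if (isInt) "MET_INT" else "MET_DOUBLE"
  writeLines(c("ObjectType = Image",
               "NDims = 3",
               "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               paste0("DimSize = ", paste(dim(data), collapse = " ")),
               paste0("ElementSpacing = ",
                      paste(rep(spacingUm, 3L), collapse = " ")),
               paste0("ElementType = ", ty),
               paste0("ElementDataFile = ", rawName)), path)
  con <- file(file.path(dirname(path), rawName), "wb")
  on.exit(close(con))
  if (isInt) writeBin(as.integer(data), con, size = 4L, endian = "little")
  else writeBin(as.double(data), con, size = 8L, endian = "little")
  invisible(path)
}

## ---- public IO ----------------------------------------------------------

#' Read a microCT volume
#'
#' Reads a directory of equally-sized 2D TIFF slices (lexicographic filename
#' order defines axis 1), a multi-page TIFF, an NRRD volume, or an MHD/RAW
#' pair. Intensities are returned in raw units.
#'
#' When the file header carries an (isotropic) voxel size and a
#' `voxelSizeUm` argument is also given, the argument wins and a warning is
#' emitted. Anisotropic header spacings are an error: thickness metrics
#' assume isotropic voxels and silent resampling would corrupt them.
#'
#' @param path directory of TIFF slices, or a `.tif/.tiff`, `.nrrd` or
#'   `.mhd` file.
#' @param voxelSizeUm isotropic voxel size in micrometres; may be omitted
#'   when the file header provides one.
#' @return a [GreyVolume-class] in raw units.
#' @export
readVolume <- function(path, voxelSizeUm = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  headerSpacing <- NULL
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    data <- readTiffStack(files)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(imgs)) imgs <- list(imgs)
      d <- dim(imgs[[1L]])
      data <- array(0, c(length(imgs), d[1L], d[2L]))
      for (i in seq_along(imgs)) data[i, , ] <- imgs[[i]]
    } else if (ext == "nrrd") {
      r <- readNrrd(path)
      data <- r$data
      headerSpacing <- r$spacing
    } else if (ext == "mhd") {
      r <- readMhd(path)
      data <- r$data
      headerSpacing <- r$spacing
    } else stop("unsupported volume format: ", path)
  }
  if (!is.null(headerSpacing) && length(headerSpacing) > 0L) {
    if (max(headerSpacing) - min(headerSpacing) > 1e-9 * max(headerSpacing))
      stop("anisotropic voxels are not supported (header spacing ",
           paste(headerSpacing, collapse = " x "), ")")
    hs <- headerSpacing[1L]
    if (is.null(voxelSizeUm)) {
      voxelSizeUm <- hs
    } else if (abs(hs - voxelSizeUm) > 1e-9 * voxelSizeUm) {
      warning(sprintf(
        "voxel size argument (%g um) overrides file header (%g um)",
        voxelSizeUm, hs))
    }
  }
  if (is.null(voxelSizeUm))
    stop("voxelSizeUm must be given when the file header carries none")
  if (voxelSizeUm <= 0) stop("voxel size must be positive")
  greyVolume(data, voxelSizeUm, "raw")
}

#' Write a volume to disk
#'
#' A directory path produces a 16-bit TIFF stack (`slice_0001.tif`, ...);
#' integer intensities in `[0, 65535]` round-trip exactly through
#' [readVolume()]. Paths ending in `.nrrd` or `.mhd` write single-file
#' volumes that round-trip any numeric data exactly (doubles for
#' non-integer data).
#'
#' @param v a [GreyVolume-class].
#' @param path output directory (TIFF stack) or `.nrrd`/`.mhd` file path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "GreyVolume"))
  data <- v@data
  if (any(dim(data) < 1L)) stop("empty-extent volume")
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") return(invisible(writeNrrd(data, path, v@voxelSizeUm)))
  if (ext == "mhd") return(invisible(writeMhd(data, path, v@voxelSizeUm)))
  if (nzchar(ext)) stop("unsupported output format: .", ext)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (any(data != round(data)) || min(data) < 0 || max(data) > 65535)
    stop("TIFF stacks require integer intensities in [0, 65535]; ",
         "use an .nrrd path for real-valued or out-of-range volumes")
  for (i in seq_len(dim(data)[1L])) {
    tiff::writeTIFF(data[i, , ] / 65535,
                    file.path(path, sprintf("slice_%04d.tif", i)),
                    bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF stack (0/255)
#'
#' @param m a [VoxelMask-class].
#' @param path output directory.
#' @return the path, invisibly.
#' @export
writeMask <- function(m, path) {
  stopifnot(is(m, "VoxelMask"))
  if (any(dim(m@data) < 1L)) stop("empty-extent mask")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (i in seq_len(dim(m@data)[1L])) {
    tiff::writeTIFF(m@data[i, , ] * 1.0,
                    file.path(path, sprintf("slice_%04d.tif", i)),
                    bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read a binary mask written by [writeMask()]
#'
#' @param path directory of 8-bit TIFF slices.
#' @param voxelSizeUm isotropic voxel size in micrometres.
#' @param label compartment label for the result.
#' @return a [VoxelMask-class].
#' @export
readMask <- function(path, voxelSizeUm, label = "") {
  v <- readVolume(path, voxelSizeUm)
  voxelMask(v@data > 0, voxelSizeUm, label)
}

#' Re-slice a volume to the coronal orientation
#'
#' Pure axis permutation (no resampling). The declared source orientation
#' fixes the interpretation of the input axes: `axial` stacks iterate
#' transverse planes (axis 1 proximal to distal, axis 2 AP, axis 3 ML);
#' `sagittal` stacks iterate sagittal planes (axis 1 ML, axis 2 vertical,
#' axis 3 AP). Both permutations are involutions, so re-applying the same
#' permutation restores the original stack. Coronal input is returned as an
#' identical copy.
#'
#' @param v a [GreyVolume-class].
#' @param sourceOrientation `"axial"`, `"sagittal"` or `"coronal"`.
#' @return a [GreyVolume-class] in the coronal axes convention.
#' @export
resliceCoronal <- function(v,
                           sourceOrientation = c("coronal", "axial",
                                                 "sagittal")) {
  stopifnot(is(v, "GreyVolume"))
  sourceOrientation <- match.arg(sourceOrientation)
  data <- switch(sourceOrientation,
    coronal = v@data,
    axial = aperm(v@data, c(2L, 1L, 3L)),
    sagittal = aperm(v@data, c(3L, 2L, 1L)))
  greyVolume(data, v@voxelSizeUm, v@intensityUnits)
}

#' Calibrate raw intensities to Hounsfield units
#'
#' Two-point affine calibration `HU(x) = 1000 * (x - w) / (w - a)` against
#' the mean raw intensity `w` of the immersion-fluid (water-equivalent)
#' reference and `a` of an air reference, so that the fluid maps to 0 HU and
#' air to -1000 HU.
#'
#' @param v a [GreyVolume-class] in raw units.
#' @param cal an [HUCalibration-class].
#' @return a [GreyVolume-class] with `intensityUnits == "HU"`.
#' @export
calibrateHU <- function(v, cal) {
  stopifnot(is(v, "GreyVolume"), is(cal, "HUCalibration"))
  if (v@intensityUnits != "raw")
    stop("volume is already calibrated (units: ", v@intensityUnits, ")")
  w <- cal@meanWaterEquivalent
  a <- cal@meanAir
  greyVolume(1000 * (v@data - w) / (w - a), v@voxelSizeUm, "HU")
}
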