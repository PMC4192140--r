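#' Voxel data of a volume or mask
#' @param object a [GreyVolume-class], [VoxelMask-class] or
#'   [ThicknessField-class].
#' @return a 3D array (numeric or logical).
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' Isotropic voxel size in micrometres
#' @param object an object carrying voxel-size metadata.
#' @return a single positive number (um).
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' Intensity units of a volume
#' @param object a [GreyVolume-class].
#' @return `"raw"` or `"HU"`.
#' @export
setGeneric("intensityUnits", function(object)
  standardGeneric("intensityUnits"))

#' @describeIn voxelData intensities of a grey volume
#' @export
setMethod("voxelData", "GreyVolume", function(object) object@data)
#' @describeIn voxelData logical grid of a mask
#' @export
setMethod("voxelData", "VoxelMask", function(object) object@data)
#' @describeIn voxelData thickness values (um, `NA` off the mask)
#' @export
setMethod("voxelData", "ThicknessField", function(object) object@values)

#' @describeIn voxelSize voxel size of a grey volume
#' @export
setMethod("voxelSize", "GreyVolume", function(object) object@voxelSizeUm)
#' @describeIn voxelSize voxel size of a mask
#' @export
setMethod("voxelSize", "VoxelMask", function(object) object@voxelSizeUm)
#' @describeIn voxelSize voxel size of a thickness field
#' @export
setMethod("voxelSize", "ThicknessField", function(object) object@voxelSizeUm)
#' @describeIn voxelSize voxel size underlying a thickness map
#' @export
setMethod("voxelSize", "ThicknessMap", function(object) object@voxelSizeUm)

#' @describeIn intensityUnits units of a grey volume
#' @export
setMethod("intensityUnits", "GreyVolume", function(object)
  object@intensityUnits)

setMethod("show", "GreyVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("GreyVolume %d x %d x %d (AP x vert x ML), %g um/voxel, %s\n",
              d[1], d[2], d[3], object@voxelSizeUm, object@intensityUnits))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelMask '%s' %d x %d x %d, %g um/voxel, %d voxels set\n",
              object@label, d[1], d[2], d[3], object@voxelSizeUm,
              sum(object@data)))
})

setMethod("show", "ROIBox", function(object) {
  r <- object@ranges
  cat(sprintf(
    "ROIBox (%s): AP [%d,%d) vert [%d,%d) ML [%d,%d), footprint %g x %g um\n",
    object@side, r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3],
    object@footprintUm[1], object@footprintUm[2]))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult (%s): thresholds %s; cartilage %d vx, mineralized %d vx\n",
    object@method, paste(signif(object@thresholds, 6), collapse = ", "),
    sum(object@cartilage@data), sum(object@mineralized@data)))
})

setMethod("show", "ThicknessField", function(object) {
  v <- object@values
  cat(sprintf(
    "ThicknessField: %d defined voxels, mean %.1f um, max %.1f um\n",
    sum(!is.na(v)), mean(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap (%s) %d x %d (AP x ML), max %.1f um\n",
              object@statistic, nrow(object@grid), ncol(object@grid),
              max(object@grid, na.rm = TRUE)))
})

setMethod("show", "UptakeSeries", function(object) {
  cat(sprintf("UptakeSeries: %d time points, %.2g-%.2g h\n",
              length(object@timesH), min(object@timesH),
              max(object@timesH)))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic %.4g, p = %.4g\n", object@testName,
              object@statistic, object@pValue))
  if (!anyNA(object@ci95))
    cat(sprintf("  95%% CI [%.4g, %.4g]\n", object@ci95[1], object@ci95[2]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %s voxels at %g um, shells (%g, %g) um, tilt %g deg, seed %d\n",
    paste(object@extents, collapse = " x "), object@voxelSizeUm,
    object@shellThicknessUm[1], object@shellThicknessUm[2],
    object@tiltDeg, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: cartilage %d vx, bone %d vx, shells (%g, %g) um, tilt %g deg\n",
    sum(object@cartilageMask@data), sum(object@boneMask@data),
    object@shellThicknessUm[1], object@shellThicknessUm[2], object@tiltDeg))
})
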