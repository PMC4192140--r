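#' @useDynLib cartct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Fixed axes convention used throughout the package, for every GreyVolume
## and VoxelMask in coronal orientation:
##   axis 1 - coronal slice index, anterior -> posterior (AP)
##   axis 2 - proximal -> distal, increasing downward (vertical)
##   axis 3 - medial -> lateral (ML)

#' GreyVolume: a 3D grey-level microCT volume
#'
#' Container for a reconstructed microCT volume on an isotropic voxel grid.
#' Axis 1 iterates coronal slices (anterior to posterior), axis 2 runs
#' proximal to distal (downward), axis 3 medial to lateral. The convention is
#' fixed at construction; [resliceCoronal()] returns a new object rather than
#' mutating orientation metadata.
#'
#' @slot data 3D numeric array of voxel intensities.
#' @slot voxelSizeUm isotropic voxel edge length in micrometres.
#' @slot intensityUnits `"raw"` (scanner output) or `"HU"` (Hounsfield units
#'   after [calibrateHU()]).
#' @export
setClass("GreyVolume",
  representation(data = "array", voxelSizeUm = "numeric",
                 intensityUnits = "character"),
  prototype(voxelSizeUm = 5, intensityUnits = "raw"))

setValidity("GreyVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all three grid extents must be >= 1")
  if (length(object@voxelSizeUm) != 1L || !is.finite(object@voxelSizeUm) ||
      object@voxelSizeUm <= 0)
    return("voxelSizeUm must be a single positive number")
  if (!object@intensityUnits %in% c("raw", "HU"))
    return("intensityUnits must be 'raw' or 'HU'")
  TRUE
})

#' VoxelMask: a binary voxel mask
#'
#' Logical 3D grid aligned with a parent [GreyVolume-class] (same extents,
#' same axes convention), labelling one tissue compartment.
#'
#' @slot data 3D logical array.
#' @slot voxelSizeUm isotropic voxel edge length in micrometres.
#' @slot label free-text compartment label (e.g. `"cartilage"`).
#' @export
setClass("VoxelMask",
  representation(data = "array", voxelSizeUm = "numeric",
                 label = "character"),
  prototype(voxelSizeUm = 5, label = ""))

setValidity("VoxelMask", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all three grid extents must be >= 1")
  if (!is.logical(object@data)) return("data must be logical")
  if (length(object@voxelSizeUm) != 1L || object@voxelSizeUm <= 0)
    return("voxelSizeUm must be a single positive number")
  TRUE
})

#' HUCalibration: two-point Hounsfield calibration
#'
#' Mean raw intensities of two reference regions: the immersion fluid
#' (water-equivalent, mapped to 0 HU) and air/background (mapped to
#' -1000 HU).
#'
#' @slot meanWaterEquivalent mean raw intensity of the fluid reference.
#' @slot meanAir mean raw intensity of the air reference.
#' @export
setClass("HUCalibration",
  representation(meanWaterEquivalent = "numeric", meanAir = "numeric"))

setValidity("HUCalibration", function(object) {
  if (length(object@meanWaterEquivalent) != 1L ||
      length(object@meanAir) != 1L)
    return("reference means must be single numbers")
  if (!(object@meanWaterEquivalent > object@meanAir))
    return("meanWaterEquivalent must exceed meanAir")
  TRUE
})

#' ROIBox: an axis-aligned condylar region of interest
#'
#' Half-open voxel index box (0-based, `[start, end)` per axis, axes in the
#' package convention) with an anatomical side label. The standard condylar
#' footprint is 500 um wide (ML) by 800 um long (AP).
#'
#' @slot ranges 2 x 3 integer matrix; row 1 = start (inclusive, 0-based),
#'   row 2 = end (exclusive), columns = axes (AP, vertical, ML).
#' @slot side `"medial"` or `"lateral"`.
#' @slot footprintUm numeric length 2: (width ML, length AP) in micrometres.
#' @export
setClass("ROIBox",
  representation(ranges = "matrix", side = "character",
                 footprintUm = "numeric"))

setValidity("ROIBox", function(object) {
  r <- object@ranges
  if (!is.numeric(r) || !all(dim(r) == c(2L, 3L)))
    return("ranges must be a 2 x 3 matrix (start; end) x (axes)")
  if (any(r[2L, ] <= r[1L, ])) return("end must exceed start on every axis")
  if (any(r[1L, ] < 0)) return("ranges must be non-negative (0-based)")
  if (!object@side %in% c("medial", "lateral"))
    return("side must be 'medial' or 'lateral'")
  TRUE
})

#' JointLandmarks: automatically detected tibial landmarks
#'
#' @slot topEdge AP x ML numeric matrix; per column, the smallest vertical
#'   (axis 2) 0-based index of a foreground voxel, `NA` where the column
#'   contains none.
#' @slot symmetryAxisML sub-voxel ML column index (0-based) of the condylar
#'   mirror-symmetry axis.
#' @slot midCoronalAP AP midpoint (0-based slice index) of the foreground.
#' @slot condyleCentres 2 x 2 matrix, rows medial/lateral, columns (AP, ML).
#' @export
setClass("JointLandmarks",
  representation(topEdge = "matrix", symmetryAxisML = "numeric",
                 midCoronalAP = "numeric", condyleCentres = "matrix"))

#' ThicknessField: per-voxel local thickness
#'
#' Local thickness in micrometres, defined on the mask voxels (`NA`
#' elsewhere): at voxel p, the diameter of the largest sphere fully inscribed
#' in the mask that contains p.
#'
#' @slot values 3D numeric array, um; `NA` off the mask.
#' @slot voxelSizeUm voxel edge length in micrometres.
#' @export
setClass("ThicknessField",
  representation(values = "array", voxelSizeUm = "numeric"))

#' ThicknessMap: planar projection of a thickness field
#'
#' Per (AP, ML) column, the max (default) or mean of the defined thickness
#' values along the vertical axis; `NA` where the mask does not project.
#'
#' @slot grid AP x ML numeric matrix, micrometres.
#' @slot statistic `"max"` or `"mean"`.
#' @slot voxelSizeUm voxel edge length in micrometres.
#' @export
setClass("ThicknessMap",
  representation(grid = "matrix", statistic = "character",
                 voxelSizeUm = "numeric"))

setValidity("ThicknessMap", function(object) {
  if (!object@statistic %in% c("max", "mean"))
    return("statistic must be 'max' or 'mean'")
  TRUE
})

#' SegmentationResult: cartilage and mineralized masks plus thresholds
#'
#' @slot cartilage [VoxelMask-class] of the stained cartilage layer.
#' @slot mineralized [VoxelMask-class] of the mineralized compartment.
#' @slot thresholds strictly increasing numeric thresholds.
#' @slot method `"otsu2"` or `"otsu3"`.
#' @export
setClass("SegmentationResult",
  representation(cartilage = "VoxelMask", mineralized = "VoxelMask",
                 thresholds = "numeric", method = "character"))

setValidity("SegmentationResult", function(object) {
  if (any(object@cartilage@data & object@mineralized@data))
    return("cartilage and mineralized masks must be disjoint")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    return("thresholds must be strictly increasing")
  if (!object@method %in% c("otsu2", "otsu3"))
    return("method must be 'otsu2' or 'otsu3'")
  TRUE
})

#' PhantomSpec: parameters of the synthetic tibia phantom
#'
#' Describes a bone plateau carrying two spherical-cap condyles, each coated
#' by a cartilage shell of known thickness, plus grey levels, blur, noise and
#' condylar-axis tilt. Defaults reproduce the package's reference imaging
#' conditions: 5 um voxels, 60 um shells, condylar ROI-compatible geometry,
#' and grey levels giving 85% cartilage/background and 35% cartilage/plate
#' contrast.
#'
#' @slot extents grid extents (AP, vertical, ML).
#' @slot voxelSizeUm voxel edge length, um.
#' @slot condyleRadiusUm condyle (bone dome) radius, um.
#' @slot condyleCentresML ML offsets of the medial/lateral condyle centres
#'   from the grid ML midline, um (medial negative).
#' @slot shellThicknessUm cartilage shell thickness per side
#'   (medial, lateral), um.
#' @slot greyBkg,greyBone,greyCartilage class grey levels
#'   (cartilage > bone > background).
#' @slot noiseSd additive Gaussian noise SD (grey units).
#' @slot blurSigmaUm Gaussian blur sigma, um.
#' @slot tiltDeg rotation of the condyle-pair axis about the vertical, deg.
#' @slot seed RNG seed for the noise realisation.
#' @export
setClass("PhantomSpec",
  representation(extents = "integer", voxelSizeUm = "numeric",
                 condyleRadiusUm = "numeric", condyleCentresML = "numeric",
                 shellThicknessUm = "numeric", greyBkg = "numeric",
                 greyBone = "numeric", greyCartilage = "numeric",
                 noiseSd = "numeric", blurSigmaUm = "numeric",
                 tiltDeg = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@extents) != 3L || any(object@extents < 1L))
    return("extents must be 3 positive integers")
  if (object@voxelSizeUm <= 0) return("voxelSizeUm must be positive")
  if (!(object@greyCartilage > object@greyBone &&
        object@greyBone > object@greyBkg))
    return("grey levels must satisfy cartilage > bone > background")
  if (length(object@shellThicknessUm) != 2L ||
      any(object@shellThicknessUm < 2 * object@voxelSizeUm))
    return("shell thickness must be >= 2 voxels per side")
  if (object@noiseSd < 0 || object@blurSigmaUm < 0)
    return("noiseSd and blurSigmaUm must be non-negative")
  TRUE
})

#' PhantomTruth: ground truth emitted with each phantom
#'
#' @slot cartilageMask,boneMask disjoint [VoxelMask-class] objects computed
#'   before blur and noise.
#' @slot shellThicknessUm (medial, lateral) shell thickness, um.
#' @slot condyleCentres 2 x 3 matrix (rows medial/lateral) of condyle sphere
#'   centres in 0-based voxel coordinates (AP, vertical, ML).
#' @slot tiltDeg programmed condylar-axis tilt, degrees.
#' @slot thinningFactor (medial, lateral) factor in (0, 1] applied to the
#'   shells relative to the un-thinned reference.
#' @slot cutParameters numeric of length 3 `(positionAP_um, width_um,
#'   depth_um)` when a scalpel cut was applied, length 0 otherwise.
#' @slot apexDepthUm per-voxel depth below the cartilage surface, um
#'   (`NA` off the cartilage mask); used by the uptake simulator.
#' @export
setClass("PhantomTruth",
  representation(cartilageMask = "VoxelMask", boneMask = "VoxelMask",
                 shellThicknessUm = "numeric", condyleCentres = "matrix",
                 tiltDeg = "numeric", thinningFactor = "numeric",
                 cutParameters = "numeric", apexDepthUm = "array"))

setValidity("PhantomTruth", function(object) {
  if (any(object@cartilageMask@data & object@boneMask@data))
    return("cartilage and bone truth masks must be disjoint")
  TRUE
})

#' UptakeSeries: contrast-uptake time course
#'
#' @slot timesH increasing acquisition times, hours.
#' @slot meanAC,meanBKG,meanSCP per-time mean intensities of the cartilage,
#'   background and subchondral-plate regions.
#' @slot sbrAcBkg,sbrAcScp signal-to-background ratios, percent.
#' @export
setClass("UptakeSeries",
  representation(timesH = "numeric", meanAC = "numeric", meanBKG = "numeric",
                 meanSCP = "numeric", sbrAcBkg = "numeric",
                 sbrAcScp = "numeric"))

setValidity("UptakeSeries", function(object) {
  n <- length(object@timesH)
  if (is.unsorted(object@timesH, strictly = TRUE))
    return("timesH must be strictly increasing")
  for (s in c("meanAC", "meanBKG", "meanSCP", "sbrAcBkg", "sbrAcScp"))
    if (length(slot(object, s)) != n)
      return("all series must have the same length as timesH")
  TRUE
})

#' TestResult: outcome of a statistical comparison
#'
#' @slot statistic test statistic.
#' @slot pValue two-sided p-value in `[0, 1]`.
#' @slot dof degrees of freedom (`NA` for exact nonparametric tests).
#' @slot ci95 95% confidence interval of the estimated difference
#'   (length 2, `NA` when not defined).
#' @slot testName human-readable test name.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", pValue = "numeric", dof = "numeric",
                 ci95 = "numeric", testName = "character"))

setValidity("TestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must be in [0, 1]")
  TRUE
})
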