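#' Mean intensity of a region
#'
#' @param v a [GreyVolume-class].
#' @param region a [VoxelMask-class] or [ROIBox-class]; must intersect the
#'   grid in at least one voxel.
#' @return arithmetic mean intensity.
#' @export
regionMean <- function(v, region) {
  stopifnot(is(v, "GreyVolume"))
  if (is(region, "VoxelMask")) {
    if (!any(region@data)) stop("empty region")
    return(mean(v@data[region@data]))
  }
  if (is(region, "ROIBox")) {
    idx <- boxIndices(region, dim(v@data))
    vals <- v@data[idx[[1L]], idx[[2L]], idx[[3L]]]
    if (length(vals) == 0L) stop("empty region")
    return(mean(vals))
  }
  stop("region must be a VoxelMask or ROIBox")
}

#' Signal-to-background ratio
#'
#' Percent contrast of a region relative to a reference region:
#' `100 * (signal - reference) / reference`. Scale-invariant and zero when
#' signal equals reference.
#'
#' @param signalMean mean intensity of the region of interest.
#' @param referenceMean mean intensity of the reference region; must be
#'   positive.
#' @return contrast in percent.
#' @export
sbr <- function(signalMean, referenceMean) {
  if (any(referenceMean <= 0)) stop("reference mean must be positive")
  100 * (signalMean - referenceMean) / referenceMean
}

#' Contrast-uptake time course over an image series
#'
#' Computes per-time mean intensities of the cartilage (AC), background
#' (BKG) and subchondral-plate (SCP) regions, and the two contrast curves
#' SBR(AC vs BKG) and SBR(AC vs SCP).
#'
#' @param volumes list of [GreyVolume-class] on a common grid, one per
#'   time point.
#' @param timesH strictly increasing acquisition times, hours.
#' @param regionAC,regionBKG,regionSCP fixed regions ([VoxelMask-class] or
#'   [ROIBox-class]).
#' @return an [UptakeSeries-class].
#' @export
uptakeTimecourse <- function(volumes, timesH, regionAC, regionBKG,
                             regionSCP) {
  stopifnot(length(volumes) == length(timesH), length(volumes) >= 1L)
  d <- dim(volumes[[1L]]@data)
  for (v in volumes)
    if (!identical(dim(v@data), d)) stop("mismatched grids in series")
  mAC <- vapply(volumes, regionMean, numeric(1L), region = regionAC)
  mBKG <- vapply(volumes, regionMean, numeric(1L), region = regionBKG)
  mSCP <- vapply(volumes, regionMean, numeric(1L), region = regionSCP)
  new("UptakeSeries", timesH = as.numeric(timesH), meanAC = mAC,
      meanBKG = mBKG, meanSCP = mSCP,
      sbrAcBkg = sbr(mAC, mBKG), sbrAcScp = sbr(mAC, mSCP))
}

#' Detect the uptake plateau time
#'
#' Earliest sampled time from which the AC mean stays within
#' `toleranceFraction` of its final value for all later samples. If only
#' the final sample itself qualifies, the series has not plateaued inside
#' the sampled window and an error is raised.
#'
#' @param series an [UptakeSeries-class] with at least 3 time points.
#' @param toleranceFraction relative tolerance band around the final AC
#'   mean.
#' @return plateau time in hours.
#' @export
detectPlateau <- function(series, toleranceFraction = 0.05) {
  stopifnot(is(series, "UptakeSeries"))
  n <- length(series@timesH)
  if (n < 3L) stop("need at least 3 time points")
  final <- series@meanAC[n]
  inBand <- abs(series@meanAC - final) <= toleranceFraction * abs(final)
  ## suffix-stable: all samples from i onward must be inside the band
  stable <- rev(cumprod(rev(inBand))) > 0
  first <- which(stable)[1L]
  if (first == n)
    stop("series never enters the tolerance band before its final sample")
  series@timesH[first]
}
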