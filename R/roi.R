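## round-half-away-from-zero, applied once to um -> voxel conversions so box
## sizes are bit-reproducible
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct an ROIBox
#'
#' @param start 0-based inclusive start indices (AP, vertical, ML).
#' @param size extents in voxels per axis.
#' @param side `"medial"` or `"lateral"`.
#' @param footprintUm (width ML, length AP) in micrometres.
#' @return an [ROIBox-class] (half-open `[start, start + size)`).
#' @export
roiBox <- function(start, size, side, footprintUm = c(500, 800)) {
  ranges <- rbind(as.numeric(start), as.numeric(start) + as.numeric(size))
  new("ROIBox", ranges = ranges, side = side,
      footprintUm = as.numeric(footprintUm))
}

## 1-based index list for subsetting R arrays with a half-open 0-based box
boxIndices <- function(box, dims = NULL) {
  r <- box@ranges
  lapply(1:3, function(a) {
    lo <- r[1L, a] + 1L
    hi <- r[2L, a]
    if (!is.null(dims)) hi <- min(hi, dims[a])
    seq.int(lo, hi)
  })
}

#' Detect the top edge of the tibia
#'
#' For every (AP, ML) column of the foreground mask, the smallest vertical
#' (axis 2) index containing a foreground voxel — the height map of the
#' joint surface seen from above. Columns without foreground are `NA`,
#' never 0.
#'
#' @param foreground a non-empty [VoxelMask-class].
#' @return AP x ML numeric matrix of 0-based row indices (`NA` = empty
#'   column).
#' @export
detectTopEdge <- function(foreground) {
  stopifnot(is(foreground, "VoxelMask"))
  m <- foreground@data
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  ## first TRUE along axis 2: use max.col on the reversed cummax trick;
  ## straightforward apply is clear and fast enough at these sizes
  te <- apply(m, c(1L, 3L), function(col) {
    w <- which(col)
    if (length(w)) w[1L] - 1 else NA_real_
  })
  matrix(te, d[1L], d[3L])
}

## mirror-overlap score of a top-edge map about ML column c (0-based):
## negative mean squared height difference between matched column pairs.
## A defined column whose mirror is undefined (or falls outside the grid)
## counts as a full-scale mismatch, so the score cannot be gamed by
## centring the mirror on one condyle and ignoring the other side.
mirrorScore <- function(topEdge, c0) {
  nML <- ncol(topEdge)
  k <- 0:(nML - 1L)
  k2 <- 2L * c0 - k
  inGrid <- k2 >= 0L & k2 <= nML - 1L
  def <- !is.na(topEdge)
  heights <- topEdge[def]
  penalty <- (max(heights) - min(heights))^2
  if (penalty == 0) penalty <- 1
  sqsum <- 0
  npair <- 0L
  ## pairs k < k2 inside the grid
  ok <- inGrid & k < k2
  if (any(ok)) {
    a <- topEdge[, k[ok] + 1L, drop = FALSE]
    b <- topEdge[, k2[ok] + 1L, drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    one <- xor(!is.na(a), !is.na(b))
    sqsum <- sum((a[both] - b[both])^2) + penalty * sum(one)
    npair <- sum(both) + sum(one)
  }
  ## defined columns reflected outside the grid are unmatched
  off <- !inGrid
  if (any(off)) {
    nOff <- sum(def[, which(off), drop = FALSE])
    sqsum <- sqsum + penalty * nOff
    npair <- npair + nOff
  }
  if (npair == 0L) return(-Inf)
  -sqsum / npair
}

#' Estimate the condylar symmetry axis and mid-coronal plane
#'
#' The symmetry axis is the ML column about which the top-edge height map
#' best matches its own ML mirror image (exhaustive integer scan, then
#' 3-point parabolic sub-voxel refinement). The mid-coronal position is the
#' midpoint of the foreground's AP extent.
#'
#' @param foreground a non-empty [VoxelMask-class].
#' @return list with `symmetryAxisML` (sub-voxel 0-based column),
#'   `integerAxisML` (the unrefined integer maximiser), `midCoronalAP`, and
#'   `scores` (per integer candidate column).
#' @export
findSymmetryAxis <- function(foreground) {
  stopifnot(is(foreground, "VoxelMask"))
  m <- foreground@data
  if (!any(m)) stop("empty mask")
  topEdge <- detectTopEdge(foreground)
  nML <- ncol(topEdge)
  scores <- vapply(0:(nML - 1L), function(c0) mirrorScore(topEdge, c0),
                   numeric(1L))
  c0 <- which.max(scores) - 1L
  axis <- c0
  ## parabolic refinement over the three points around the integer maximum
  if (c0 >= 1L && c0 <= nML - 2L) {
    y0 <- scores[c0]
    y1 <- scores[c0 + 1L]
    y2 <- scores[c0 + 2L]
    den <- y0 - 2 * y1 + y2
    if (is.finite(den) && den < 0) axis <- c0 + 0.5 * (y0 - y2) / den
  }
  apAny <- which(apply(m, 1L, any))
  list(symmetryAxisML = axis, integerAxisML = c0,
       midCoronalAP = (min(apAny) - 1 + max(apAny) - 1) / 2,
       scores = scores)
}

#' Assemble joint landmarks from a foreground mask
#'
#' Computes the top-edge height map, the condylar symmetry axis, the
#' mid-coronal position, and per-side cartilage-column centroids (used as
#' condyle centres by ROI placement).
#'
#' @param foreground a [VoxelMask-class] (typically cartilage, or
#'   cartilage plus mineralized tissue).
#' @return a [JointLandmarks-class].
#' @export
detectLandmarks <- function(foreground) {
  topEdge <- detectTopEdge(foreground)
  sym <- findSymmetryAxis(foreground)
  centres <- matrix(NA_real_, 2L, 2L,
                    dimnames = list(c("medial", "lateral"), c("AP", "ML")))
  cols <- which(!is.na(topEdge), arr.ind = TRUE) - 1  # 0-based (AP, ML)
  for (s in 1:2) {
    onSide <- if (s == 1L) cols[, 2L] < sym$symmetryAxisML
              else cols[, 2L] > sym$symmetryAxisML
    if (any(onSide))
      centres[s, ] <- colMeans(cols[onSide, , drop = FALSE])
  }
  new("JointLandmarks", topEdge = topEdge,
      symmetryAxisML = sym$symmetryAxisML,
      midCoronalAP = sym$midCoronalAP, condyleCentres = centres)
}

#' Place the two condylar regions of interest
#'
#' One fixed-footprint box per condyle: the ML centre is the centroid of
#' the cartilage columns on that side of the symmetry axis, the AP centre
#' is the mid-coronal position, and the vertical extent runs from the
#' highest top-edge row inside the footprint down `depthUm` — covering the
#' cartilage layer, the subchondral plate and trabecular bone beneath.
#' The footprint is converted to voxels once, by round-half-away-from-zero.
#'
#' @param cart cartilage [VoxelMask-class].
#' @param landmarks a [JointLandmarks-class] from the same grid.
#' @param footprintUm (width ML, length AP), um; default the standard
#'   500 x 800 um condylar window.
#' @param depthUm vertical extent of the box, um.
#' @return list of two [ROIBox-class] objects named `medial` and `lateral`.
#' @export
placeCondyleROIs <- function(cart, landmarks, footprintUm = c(500, 800),
                             depthUm = 400) {
  stopifnot(is(cart, "VoxelMask"), is(landmarks, "JointLandmarks"))
  vox <- cart@voxelSizeUm
  d <- dim(cart@data)
  wML <- roundHalfAway(footprintUm[1L] / vox)
  lAP <- roundHalfAway(footprintUm[2L] / vox)
  dVox <- roundHalfAway(depthUm / vox)
  proj <- !is.na(landmarks@topEdge) &
          matrix(apply(cart@data, c(1L, 3L), any), d[1L], d[3L])
  cols <- which(proj, arr.ind = TRUE) - 1            # 0-based (AP, ML)
  out <- list()
  for (side in c("medial", "lateral")) {
    onSide <- if (side == "medial") {
      cols[, 2L] < landmarks@symmetryAxisML
    } else cols[, 2L] > landmarks@symmetryAxisML
    if (!any(onSide)) stop("no cartilage on the ", side, " side")
    centreML <- mean(cols[onSide, 2L])
    startML <- floor(centreML - wML / 2 + 0.5)
    startAP <- floor(landmarks@midCoronalAP - lAP / 2 + 0.5)
    ## clip the footprint to the grid
    clip <- FALSE
    if (startML < 0) { startML <- 0; clip <- TRUE }
    if (startAP < 0) { startAP <- 0; clip <- TRUE }
    if (startML + wML > d[3L]) { startML <- d[3L] - wML; clip <- TRUE }
    if (startAP + lAP > d[1L]) { startAP <- d[1L] - lAP; clip <- TRUE }
    ## top row inside the footprint
    apIdx <- startAP + seq_len(lAP)                  # 1-based rows
    mlIdx <- startML + seq_len(wML)
    te <- landmarks@topEdge[apIdx, mlIdx]
    if (all(is.na(te))) stop("ROI footprint contains no surface on the ",
                             side, " side")
    top <- min(te, na.rm = TRUE)
    if (top + dVox > d[2L]) {
      warning("ROI clipped to the grid on the ", side, " side")
      dVox2 <- d[2L] - top
    } else dVox2 <- dVox
    if (clip) warning("ROI footprint clipped to the grid on the ",
                      side, " side")
    out[[side]] <- roiBox(c(startAP, top, startML), c(lAP, dVox2, wML),
                          side, footprintUm)
  }
  out
}

#' Estimate the tilt of the condylar symmetry axis
#'
#' Locates each condyle's thickness peak as the thickness-weighted centroid
#' of the cells at or above half the side's maximum thickness (a broad,
#' noise-stable support around the peak), then reports the signed angle
#' between the ML axis (the mid-coronal direction) and the line joining the
#' two peaks, in degrees. Mirroring the map in AP flips the sign.
#'
#' @param map a [ThicknessMap-class] containing two condylar peaks.
#' @return signed angle in degrees.
#' @export
estimateSymmetryTilt <- function(map) {
  stopifnot(is(map, "ThicknessMap"))
  g <- map@grid
  def <- which(!is.na(g), arr.ind = TRUE)
  if (nrow(def) == 0L) stop("empty thickness map")
  midML <- (min(def[, 2L]) + max(def[, 2L])) / 2
  peaks <- matrix(NA_real_, 2L, 2L)
  for (s in 1:2) {
    onSide <- if (s == 1L) def[, 2L] < midML else def[, 2L] > midML
    if (!any(onSide)) stop("fewer than two condylar peaks in the map")
    cells <- def[onSide, , drop = FALSE]
    vals <- g[cells]
    keep <- vals >= 0.5 * max(vals)
    topCells <- cells[keep, , drop = FALSE]
    w <- vals[keep]
    peaks[s, ] <- c(stats::weighted.mean(topCells[, 1L], w),
                    stats::weighted.mean(topCells[, 2L], w))
  }
  dAP <- peaks[2L, 1L] - peaks[1L, 1L]
  dML <- peaks[2L, 2L] - peaks[1L, 2L]
  atan2(dAP, dML) * 180 / pi
}
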