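#' Local thickness by maximal inscribed spheres
#'
#' For every mask voxel p, the local thickness is the diameter of the
#' largest sphere fully inscribed in the mask that contains p:
#' `2 * max{ r : exists centre c with sphere(c, r) inside the mask and
#' |c - p| <= r }`. Computed via the exact Euclidean distance transform,
#' reduction to non-redundant sphere centres (the distance ridge) and
#' sphere painting; spheres must lie entirely inside the mask — the volume
#' outside the grid counts as background, there is no border clamping.
#'
#' @param m a non-empty [VoxelMask-class].
#' @return a [ThicknessField-class] with values in micrometres (`NA` off
#'   the mask).
#' @seealso [localThicknessBruteForce()] for the exhaustive reference
#'   implementation.
#' @export
localThickness <- function(m) {
  stopifnot(is(m, "VoxelMask"))
  if (!any(m@data)) stop("empty mask")
  th <- .localThicknessCpp(m@data, dim(m@data))
  th[!m@data] <- NA_real_
  new("ThicknessField", values = th * m@voxelSizeUm,
      voxelSizeUm = m@voxelSizeUm)
}

#' Exhaustive maximal-inscribed-sphere reference
#'
#' Independent brute-force evaluation of the local-thickness definition:
#' for every mask voxel, the nearest-background distance is found by
#' scanning all background voxels (and the grid border), and the thickness
#' by scanning all candidate sphere centres. Quadratic in mask size — for
#' validating [localThickness()] on small shapes only.
#'
#' @param m a non-empty [VoxelMask-class].
#' @return a [ThicknessField-class] (um, `NA` off the mask).
#' @export
localThicknessBruteForce <- function(m) {
  stopifnot(is(m, "VoxelMask"))
  if (!any(m@data)) stop("empty mask")
  th <- .localThicknessBruteCpp(m@data, dim(m@data))
  th[!m@data] <- NA_real_
  new("ThicknessField", values = th * m@voxelSizeUm,
      voxelSizeUm = m@voxelSizeUm)
}

#' Voxel-count volume of a mask inside an ROI
#'
#' Counts the mask voxels inside the half-open box and multiplies by the
#' voxel volume. Counting is integer-exact; disjoint boxes add exactly.
#'
#' @param m a [VoxelMask-class].
#' @param box an [ROIBox-class] within the grid.
#' @return volume in cubic millimetres.
#' @export
roiVolume <- function(m, box) {
  stopifnot(is(m, "VoxelMask"), is(box, "ROIBox"))
  idx <- boxIndices(box, dim(m@data))
  n <- sum(m@data[idx[[1L]], idx[[2L]], idx[[3L]]])
  n * (m@voxelSizeUm * 1e-3)^3
}

#' Mean local thickness inside an ROI
#'
#' Arithmetic mean of the thickness values over the mask voxels inside the
#' box — a volume-weighted average over the cartilage contained in the ROI.
#' The field is computed on the full mask first, so spheres are never
#' truncated by the ROI boundary.
#'
#' @param f a [ThicknessField-class].
#' @param m the [VoxelMask-class] the field was computed on.
#' @param box an [ROIBox-class]; `NULL` averages over the whole mask.
#' @return mean thickness in micrometres.
#' @export
meanThickness <- function(f, m, box = NULL) {
  stopifnot(is(f, "ThicknessField"), is(m, "VoxelMask"))
  vals <- f@values
  sel <- m@data
  if (!is.null(box)) {
    stopifnot(is(box, "ROIBox"))
    inBox <- array(FALSE, dim(sel))
    idx <- boxIndices(box, dim(sel))
    inBox[idx[[1L]], idx[[2L]], idx[[3L]]] <- TRUE
    sel <- sel & inBox
  }
  if (!any(sel)) stop("empty mask/ROI intersection")
  mean(vals[sel], na.rm = TRUE)
}

#' Project a thickness field onto the (AP, ML) plane
#'
#' Per (AP, ML) column, the maximum (default) or mean of the defined
#' thickness values along the vertical axis; `NA` where the mask does not
#' project. The column maximum highlights each condyle's peak thickness.
#'
#' @param f a [ThicknessField-class].
#' @param statistic `"max"` or `"mean"`.
#' @return a [ThicknessMap-class].
#' @export
thicknessMap <- function(f, statistic = c("max", "mean")) {
  stopifnot(is(f, "ThicknessField"))
  statistic <- match.arg(statistic)
  v <- f@values
  fun <- if (statistic == "max") {
    function(col) if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE)
  } else {
    function(col) if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  }
  g <- apply(v, c(1L, 3L), fun)
  new("ThicknessMap", grid = matrix(g, dim(v)[1L], dim(v)[3L]),
      statistic = statistic, voxelSizeUm = f@voxelSizeUm)
}

#' Extract a thickness profile from a map
#'
#' Samples the map along a named line: `"mediolateral"` runs across both
#' condyles at a fixed AP position; `"anteroposterior_medial"` and
#' `"anteroposterior_lateral"` run along AP at the ML position of the
#' respective condyle. Positions default to the relevant condyle-centre
#' coordinates of the supplied landmarks.
#'
#' @param map a [ThicknessMap-class].
#' @param line `"mediolateral"`, `"anteroposterior_medial"` or
#'   `"anteroposterior_lateral"`.
#' @param position 0-based row (mediolateral) or column (anteroposterior)
#'   index to sample at; `NULL` uses `landmarks`.
#' @param landmarks optional [JointLandmarks-class] supplying default
#'   positions.
#' @return numeric vector of thickness values (um) along the line, `NA`
#'   outside the projected mask.
#' @export
thicknessProfile <- function(map, line = c("mediolateral",
                                           "anteroposterior_medial",
                                           "anteroposterior_lateral"),
                             position = NULL, landmarks = NULL) {
  stopifnot(is(map, "ThicknessMap"))
  line <- match.arg(line)
  g <- map@grid
  if (is.null(position)) {
    if (is.null(landmarks)) stop("give either a position or landmarks")
    position <- switch(line,
      mediolateral = landmarks@midCoronalAP,
      anteroposterior_medial = landmarks@condyleCentres["medial", "ML"],
      anteroposterior_lateral = landmarks@condyleCentres["lateral", "ML"])
  }
  idx <- round(position) + 1L
  if (line == "mediolateral") {
    if (idx < 1L || idx > nrow(g)) stop("line outside map")
    g[idx, ]
  } else {
    if (idx < 1L || idx > ncol(g)) stop("line outside map")
    g[, idx]
  }
}

#' Average thickness profiles across samples
#'
#' Element-wise mean of equal-length profiles, propagating positions where
#' any profile is defined (`NA`s are ignored cell-wise).
#'
#' @param profiles list of equal-length numeric vectors.
#' @return numeric vector.
#' @export
averageProfiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  n <- unique(lengths(profiles))
  if (length(n) != 1L) stop("profiles must have equal length")
  mat <- do.call(rbind, profiles)
  out <- colMeans(mat, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-ROI morphometry summary
#'
#' Computes, for each ROI, the voxel-count volume of the mask inside the
#' box, the number of mask voxels, and the mean local thickness.
#'
#' @param m cartilage [VoxelMask-class].
#' @param field [ThicknessField-class] computed on `m`.
#' @param rois list of [ROIBox-class] (e.g. from [placeCondyleROIs()]).
#' @return data.frame with columns `side`, `volume_mm3`,
#'   `mean_thickness_um`, `n_voxels`.
#' @export
morphometryTable <- function(m, field, rois) {
  rows <- lapply(rois, function(box) {
    idx <- boxIndices(box, dim(m@data))
    nv <- sum(m@data[idx[[1L]], idx[[2L]], idx[[3L]]])
    data.frame(side = box@side,
               volume_mm3 = nv * (m@voxelSizeUm * 1e-3)^3,
               mean_thickness_um = meanThickness(field, m, box),
               n_voxels = nv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
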