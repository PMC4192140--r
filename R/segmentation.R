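#' Grey-level histogram of a volume
#'
#' Integer volumes get one unit-width bin per integer value between the data
#' minimum and maximum; real-valued volumes get 256 uniform bins over
#' `[min, max]`. Candidate segmentation thresholds are interior bin edges.
#'
#' @param v a [GreyVolume-class] or numeric array/vector.
#' @param bins number of uniform bins for real-valued data.
#' @return a `greyHistogram`: list with `edges` (length `nb + 1`), `mids`
#'   and `counts` (length `nb`).
#' @export
greyHistogram <- function(v, bins = 256L) {
  x <- if (is(v, "GreyVolume")) v@data else v
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty volume")
  lo <- min(x)
  hi <- max(x)
  isInt <- all(x == round(x))
  if (isInt) {
    mids <- seq(lo, hi)
    edges <- c(mids - 0.5, hi + 0.5)
    counts <- tabulate(as.integer(x - lo + 1), nbins = length(mids))
  } else {
    if (hi == lo) {
      mids <- lo
      edges <- c(lo - 0.5, lo + 0.5)
      counts <- length(x)
    } else {
      edges <- seq(lo, hi, length.out = bins + 1L)
      idx <- pmin(bins, pmax(1L, findInterval(x, edges,
                                              rightmost.closed = TRUE)))
      counts <- tabulate(idx, nbins = bins)
      mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
    }
  }
  structure(list(edges = edges, mids = mids, counts = counts),
            class = "greyHistogram")
}

#' @export
print.greyHistogram <- function(x, ...) {
  cat(sprintf("greyHistogram: %d bins over [%g, %g], %g observations\n",
              length(x$counts), x$edges[1L], x$edges[length(x$edges)],
              sum(x$counts)))
  invisible(x)
}

asGreyHistogram <- function(h, bins = 256L) {
  if (inherits(h, "greyHistogram")) h else greyHistogram(h, bins)
}

#' Otsu threshold of a histogram
#'
#' Returns the interior bin edge that minimises the weighted intra-class
#' variance of the two resulting grey classes (equivalently, maximises the
#' between-class variance). Candidates leaving one class empty are skipped;
#' ties are broken towards the smallest threshold.
#'
#' @param h a `greyHistogram` (or data accepted by [greyHistogram()]).
#' @return a single threshold (bin edge value).
#' @export
otsuThreshold <- function(h) {
  multiOtsu(h, 2L)
}

#' Multilevel Otsu thresholds
#'
#' Thresholds minimising the total weighted intra-class variance over all
#' partitions of the histogram into `classes` contiguous grey classes, by
#' exhaustive search over interior bin edges (feasible for the 8-bit-style
#' histograms this package produces). `classes = 2` reduces to
#' [otsuThreshold()]; `classes = 3` separates background, mineralized plate
#' and stained cartilage.
#'
#' @param h a `greyHistogram` (or data accepted by [greyHistogram()]).
#' @param classes number of grey classes (2 or 3).
#' @return increasing numeric vector of `classes - 1` thresholds
#'   (bin edges).
#' @export
multiOtsu <- function(h, classes = 3L) {
  h <- asGreyHistogram(h)
  h <- rebinHistogram(h, 1024L)
  cnt <- as.numeric(h$counts)
  nb <- length(cnt)
  if (sum(cnt > 0) < classes)
    stop("histogram must have at least `classes` non-empty bins")
  if (!classes %in% c(2L, 3L))
    stop("only 2 or 3 classes are supported")
  ## prefix sums with W[a+1] = sum of the first a bins; the between-class
  ## contribution of bins (a, b] is (S[b+1]-S[a+1])^2 / (W[b+1]-W[a+1]);
  ## maximising the summed contributions minimises the weighted
  ## intra-class variance (total variance is fixed)
  W <- c(0, cumsum(cnt))
  S <- c(0, cumsum(cnt * h$mids))
  if (classes == 2L) {
    i <- seq_len(nb - 1L)
    wl <- W[i + 1L]
    wr <- W[nb + 1L] - W[i + 1L]
    v <- ifelse(wl > 0 & wr > 0,
                S[i + 1L]^2 / wl + (S[nb + 1L] - S[i + 1L])^2 / wr, -Inf)
    if (all(!is.finite(v))) stop("all histogram mass in one bin")
    return(h$edges[which.max(v) + 1L])        # first max = smallest edge
  }
  i <- seq_len(nb - 2L)                        # lower cut candidates
  j <- seq.int(2L, nb - 1L)                    # upper cut candidates
  wl <- W[i + 1L]
  left <- ifelse(wl > 0, S[i + 1L]^2 / wl, NA_real_)
  wr <- W[nb + 1L] - W[j + 1L]
  right <- ifelse(wr > 0, (S[nb + 1L] - S[j + 1L])^2 / wr, NA_real_)
  wm <- -outer(W[i + 1L], W[j + 1L], "-")      # W[j+1] - W[i+1]
  sm <- -outer(S[i + 1L], S[j + 1L], "-")
  mid <- ifelse(wm > 0, sm^2 / wm, NA_real_)
  total <- mid + outer(left, rep(0, length(j)), "+") +
           outer(rep(0, length(i)), right, "+")
  valid <- outer(i, j, "<") & is.finite(total)
  if (!any(valid)) stop("histogram does not support 3 non-empty classes")
  total[!valid] <- -Inf
  best <- max(total)
  hits <- which(total == best, arr.ind = TRUE)
  ## ties broken towards the smallest lower, then upper, threshold
  hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
  h$edges[c(i[hit[1L]], j[hit[2L]]) + 1L]
}

## collapse an overly fine histogram to at most maxBins uniform bins so the
## exhaustive threshold search stays tractable (wide-range integer data)
rebinHistogram <- function(h, maxBins = 1024L) {
  nb <- length(h$counts)
  if (nb <= maxBins) return(h)
  lo <- h$edges[1L]
  hi <- h$edges[nb + 1L]
  edges <- seq(lo, hi, length.out = maxBins + 1L)
  idx <- pmin(maxBins, pmax(1L, findInterval(h$mids, edges,
                                             rightmost.closed = TRUE)))
  counts <- vapply(seq_len(maxBins),
                   function(b) sum(h$counts[idx == b]), numeric(1L))
  structure(list(edges = edges,
                 mids = (edges[-1L] + edges[-(maxBins + 1L)]) / 2,
                 counts = counts),
            class = "greyHistogram")
}

#' Exhaustive reference for the Otsu criterion
#'
#' Independent brute-force minimiser of the weighted intra-class variance
#' `sum_k w_k s_k^2`: every candidate partition is scored by directly
#' computing each class's weight, mean and variance from the counts.
#' Used to validate [otsuThreshold()] and [multiOtsu()], which maximise the
#' equivalent between-class criterion instead.
#'
#' @param h a `greyHistogram`.
#' @param classes 2 or 3.
#' @return thresholds as in [multiOtsu()].
#' @export
otsuBruteForce <- function(h, classes = 2L) {
  h <- asGreyHistogram(h)
  if (!classes %in% c(2L, 3L)) stop("only 2 or 3 classes are supported")
  cuts <- .otsuBruteCpp(as.numeric(h$counts), as.numeric(h$mids),
                        as.integer(classes))
  if (any(cuts < 1L)) {
    stop(if (classes == 2L) "all histogram mass in one bin"
         else "histogram does not support 3 non-empty classes")
  }
  h$edges[cuts + 1L]
}

## slice-wise hole filling in the package axes convention
## (coronal slices = axis 1) via EBImage::fillHull on a frame stack
fillHolesSlicewise <- function(mask) {
  stack <- aperm(mask * 1.0, c(2L, 3L, 1L))
  filled <- EBImage::fillHull(stack)
  aperm(filled, c(3L, 1L, 2L)) > 0
}

## drop connected components (26-connectivity) below a voxel-count floor
filterComponents <- function(mask, minVoxels) {
  if (!any(mask) || minVoxels <= 1L) return(mask)
  lab <- .labelComponents26Cpp(mask, dim(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minVoxels)
  array(lab %in% keep, dim(mask))
}

#' Segment the cartilage and mineralized compartments
#'
#' Pipeline: (1) grey thresholds by multilevel Otsu — the default `otsu3`
#' separates background, mineralized plate and stained cartilage (the
#' brightest class, reflecting the cartilage-over-plate contrast of the
#' stain); `otsu2` first splits foreground from background, then extracts
#' the brightest layer by a second Otsu split within the foreground;
#' (2) connected components below `minComponentVoxels` voxels
#' (26-connectivity) are discarded as noise speckle; (3) internal holes are
#' filled slice-wise; (4) cartilage components must be surface-adjacent:
#' each must contain a voxel with background class within
#' `surfaceGapVoxels` voxels above it (the articular surface faces the
#' immersion fluid from above; the gap absorbs the partial-volume band a
#' blurred surface produces).
#'
#' @param v a coronal [GreyVolume-class] (raw or HU).
#' @param method `"otsu3"` (default) or `"otsu2"`.
#' @param minComponentVoxels smallest component kept, voxels (default 500
#'   at 5 um voxels).
#' @param surfaceGapVoxels upward search distance for the surface-adjacency
#'   check.
#' @return a [SegmentationResult-class].
#' @export
segmentCartilage <- function(v, method = c("otsu3", "otsu2"),
                             minComponentVoxels = 500L,
                             surfaceGapVoxels = 3L) {
  stopifnot(is(v, "GreyVolume"))
  method <- match.arg(method)
  data <- v@data
  if (method == "otsu3") {
    th <- multiOtsu(greyHistogram(data), 3L)
  } else {
    t1 <- otsuThreshold(greyHistogram(data))
    fg <- data[data > t1]
    t2 <- otsuThreshold(greyHistogram(fg))
    th <- c(t1, t2)
  }
  cart <- data > th[2L]
  mine <- data > th[1L] & data <= th[2L]

  cart <- filterComponents(cart, minComponentVoxels)
  mine <- filterComponents(mine, minComponentVoxels)
  cart <- fillHolesSlicewise(cart)
  mine <- fillHolesSlicewise(mine) & !cart

  ## surface adjacency: component reaches background class from above
  ## within the allowed gap
  if (any(cart)) {
    bkg <- data <= th[1L]
    lab <- .labelComponents26Cpp(cart, dim(cart))
    nj <- dim(cart)[2L]
    up <- array(FALSE, dim(cart))
    for (g in seq_len(surfaceGapVoxels)) {
      up[, seq_len(g), ] <- TRUE                     # outside grid = bkg
      keepRows <- seq_len(nj - g)
      up[, keepRows + g, ] <- up[, keepRows + g, , drop = FALSE] |
        bkg[, keepRows, , drop = FALSE]
    }
    touching <- unique(lab[cart & up])
    cart <- array(lab %in% touching[touching > 0L], dim(cart))
  }
  if (!any(cart)) stop("empty cartilage class after cleanup")

  new("SegmentationResult",
      cartilage = voxelMask(cart, v@voxelSizeUm, "cartilage"),
      mineralized = voxelMask(mine, v@voxelSizeUm, "mineralized"),
      thresholds = as.numeric(th), method = method)
}

#' Intensity profile along a line with zone transitions
#'
#' Samples the volume along the segment from `start` to `end` (1-based
#' voxel coordinates, nearest-voxel lookup) at approximately unit-voxel
#' steps — the number of samples is the Euclidean length in voxels, rounded
#' up — and locates the zone transitions where the profile crosses the
#' segmentation thresholds. For a downward line through the joint the
#' ordered transitions are background to cartilage (articular surface) and
#' cartilage to plate: the detected tidemark.
#'
#' @param v a [GreyVolume-class].
#' @param start,end numeric length-3 voxel coordinates (AP, vertical, ML),
#'   1-based.
#' @param thresholds increasing numeric thresholds, e.g. from
#'   [segmentCartilage()].
#' @return list with `distanceVox` (position of each sample along the
#'   line), `intensity`, `class` (integer zone per sample, 1 = below first
#'   threshold), and `transitions` (data.frame: `position`, `from`, `to`).
#' @export
boundaryProfile <- function(v, start, end, thresholds) {
  stopifnot(is(v, "GreyVolume"), length(start) == 3L, length(end) == 3L)
  d <- dim(v@data)
  if (any(start < 1) || any(end < 1) || any(start > d) || any(end > d))
    stop("line outside grid")
  len <- sqrt(sum((end - start)^2))
  if (len == 0) stop("degenerate line")
  n <- ceiling(len)
  tt <- seq(0, 1, length.out = max(n, 2L))
  pts <- cbind(start[1L] + tt * (end[1L] - start[1L]),
               start[2L] + tt * (end[2L] - start[2L]),
               start[3L] + tt * (end[3L] - start[3L]))
  idx <- cbind(pmin(d[1L], pmax(1L, round(pts[, 1L]))),
               pmin(d[2L], pmax(1L, round(pts[, 2L]))),
               pmin(d[3L], pmax(1L, round(pts[, 3L]))))
  inten <- v@data[idx]
  zone <- findInterval(inten, sort(thresholds)) + 1L
  chg <- which(diff(zone) != 0L)
  transitions <- data.frame(position = tt[chg + 1L] * len,
                            from = zone[chg], to = zone[chg + 1L])
  list(distanceVox = tt * len, intensity = inten, class = zone,
       transitions = transitions)
}
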