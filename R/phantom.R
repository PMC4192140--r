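#' Specify a synthetic tibia phantom
#'
#' The phantom emulates the grey-level structure the analysis pipeline
#' assumes: a mineralized plateau carrying two spherical-cap condyles
#' (medial, lateral), each coated by a cartilage shell of known thickness,
#' brighter than the plate, which is brighter than background — the contrast
#' ordering of stained cartilage over the subchondral plate over the
#' immersion fluid. Spherical geometry keeps the ground-truth shell
#' thickness analytic.
#'
#' Defaults encode the package's reference conditions: 5 um voxels, 60 um
#' shells, 250 um condyles offset +-325 um from the ML midline, grey levels
#' (background 100, plate 185/1.35, cartilage 185) chosen so the noise-free
#' cartilage/background contrast is 85% and cartilage/plate contrast is 35%,
#' additive noise with SD equal to 10% of the plate-background separation,
#' and a 1-voxel blur.
#'
#' @param extents grid extents (AP, vertical, ML), voxels.
#' @param voxelSizeUm isotropic voxel size, um.
#' @param condyleRadiusUm bone dome radius, um.
#' @param condyleCentresML ML offsets (medial, lateral) of the dome centres
#'   from the grid ML midline, um; medial negative.
#' @param shellThicknessUm cartilage shell thickness (medial, lateral), um.
#' @param greyBkg,greyBone,greyCartilage class grey levels
#'   (cartilage > bone > background).
#' @param noiseSd additive Gaussian noise SD, grey units.
#' @param blurSigmaUm Gaussian blur sigma, um.
#' @param tiltDeg rotation of the condyle-pair axis about the vertical, deg.
#' @param seed integer RNG seed for the noise realisation.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(extents = c(180L, 96L, 280L),
                        voxelSizeUm = 5,
                        condyleRadiusUm = 250,
                        condyleCentresML = c(-325, 325),
                        shellThicknessUm = c(60, 60),
                        greyBkg = 100,
                        greyBone = 185 / 1.35,
                        greyCartilage = 185,
                        noiseSd = 0.1 * (185 / 1.35 - 100),
                        blurSigmaUm = 5,
                        tiltDeg = 0,
                        seed = 1L) {
  new("PhantomSpec", extents = as.integer(extents),
      voxelSizeUm = as.numeric(voxelSizeUm),
      condyleRadiusUm = as.numeric(condyleRadiusUm),
      condyleCentresML = as.numeric(condyleCentresML),
      shellThicknessUm = as.numeric(shellThicknessUm),
      greyBkg = as.numeric(greyBkg), greyBone = as.numeric(greyBone),
      greyCartilage = as.numeric(greyCartilage),
      noiseSd = as.numeric(noiseSd), blurSigmaUm = as.numeric(blurSigmaUm),
      tiltDeg = as.numeric(tiltDeg), seed = as.integer(seed))
}

## Geometry shared by the generator and the cut/uptake variants. Returns the
## class-label array, truth masks, per-voxel shell depth and condyle centres,
## all before blur/noise.
phantomGeometry <- function(spec) {
  d <- spec@extents
  vox <- spec@voxelSizeUm
  rb <- spec@condyleRadiusUm
  tS <- spec@shellThicknessUm

  ## plateau top row: leave the dome plus shell plus blur margin above it
  margin <- ceiling(3 * spec@blurSigmaUm / vox) + 2
  topNeed <- (rb + max(tS)) / vox + margin
  plateauRow <- ceiling(topNeed)
  if (plateauRow >= d[2L] - 2L)
    stop("domes exceed grid: increase the vertical extent")

  midAP <- (d[1L] - 1) / 2
  midML <- (d[3L] - 1) / 2
  th <- spec@tiltDeg * pi / 180
  offv <- spec@condyleCentresML / vox
  centres <- cbind(AP = midAP + offv * sin(th),
                   vert = rep(plateauRow, 2L),
                   ML = midML + offv * cos(th))
  rownames(centres) <- c("medial", "lateral")

  sep <- sqrt(sum((centres[1L, c(1L, 3L)] - centres[2L, c(1L, 3L)])^2)) * vox
  if (sep < 2 * rb + sum(tS)) stop("condyles overlapping")
  for (s in 1:2) {
    reach <- (rb + tS[s]) / vox
    if (centres[s, 1L] - reach < 0 || centres[s, 1L] + reach > d[1L] - 1 ||
        centres[s, 3L] - reach < 0 || centres[s, 3L] + reach > d[3L] - 1 ||
        centres[s, 2L] - reach < 0)
      stop("domes exceed grid")
  }

  i <- (seq_len(d[1L]) - 1)            # AP, voxels
  j <- (seq_len(d[2L]) - 1)            # vertical
  k <- (seq_len(d[3L]) - 1)            # ML

  ## squared distances (um^2) to each dome centre, as 3D arrays
  dist2 <- function(s) {
    di2 <- (i - centres[s, 1L])^2
    dj2 <- (j - centres[s, 2L])^2
    dk2 <- (k - centres[s, 3L])^2
    (outer(outer(di2, dj2, "+"), dk2, "+")) * vox^2
  }
  d2m <- dist2(1L)
  d2l <- dist2(2L)
  nearestMedial <- d2m <= d2l
  r <- sqrt(ifelse(nearestMedial, d2m, d2l))
  tHere <- ifelse(nearestMedial, tS[1L], tS[2L])

  abovePlateau <- array(rep(j < plateauRow, each = d[1L]), d)
  dome <- r <= rb & abovePlateau
  slab <- array(rep(j >= plateauRow, each = d[1L]), d)
  bone <- slab | dome
  cart <- abovePlateau & r > rb & r <= rb + tHere

  depth <- array(NA_real_, d)
  depth[cart] <- (rb + tHere - r)[cart]

  labels <- array(1L, d)               # 1 bkg, 2 bone, 3 cartilage
  labels[bone] <- 2L
  labels[cart] <- 3L

  list(labels = labels, cart = cart, bone = bone, depth = depth,
       centres = centres, plateauRow = plateauRow)
}

## blur + seeded noise on a class-grey volume
phantomRender <- function(classGrey, spec, seedOffset = 0L) {
  vox <- spec@voxelSizeUm
  out <- classGrey
  if (spec@blurSigmaUm > 0)
    out <- .gaussianBlur3dCpp(out, dim(out), spec@blurSigmaUm / vox)
  if (spec@noiseSd > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec@seed + seedOffset)
    out <- out + array(stats::rnorm(length(out), sd = spec@noiseSd),
                       dim(out))
  }
  out
}

phantomClassGrey <- function(labels, spec) {
  g <- array(spec@greyBkg, dim(labels))
  g[labels == 2L] <- spec@greyBone
  g[labels == 3L] <- spec@greyCartilage
  g
}

makeTruth <- function(geo, spec, thinningFactor = c(1, 1),
                      cutParameters = numeric(0)) {
  vox <- spec@voxelSizeUm
  new("PhantomTruth",
      cartilageMask = voxelMask(geo$cart, vox, "cartilage"),
      boneMask = voxelMask(geo$bone, vox, "mineralized"),
      shellThicknessUm = spec@shellThicknessUm,
      condyleCentres = geo$centres,
      tiltDeg = spec@tiltDeg,
      thinningFactor = thinningFactor,
      cutParameters = cutParameters,
      apexDepthUm = geo$depth)
}

#' Generate a synthetic tibia phantom
#'
#' Builds the grey-level volume (class greys, then Gaussian blur, then
#' seeded additive noise) together with its ground truth (masks computed
#' before blur/noise, analytic shell thicknesses, condyle centres, tilt).
#' Generation is a pure function of the spec: the same spec always yields a
#' bit-identical volume.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([GreyVolume-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @export
makeTibiaPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  geo <- phantomGeometry(spec)
  vol <- phantomRender(phantomClassGrey(geo$labels, spec), spec)
  list(volume = greyVolume(vol, spec@voxelSizeUm, "raw"),
       truth = makeTruth(geo, spec))
}

#' Thin one condyle's cartilage shell
#'
#' Regenerates the phantom with the chosen side's shell thickness multiplied
#' by `factor`, emulating the focal cartilage loss produced by joint
#' destabilisation; the other side is untouched and the factor is recorded
#' in the truth.
#'
#' @param spec the [PhantomSpec-class] of the un-thinned phantom.
#' @param factor thinning factor in (0, 1].
#' @param side `"medial"` or `"lateral"`.
#' @return list with `volume`, `truth` and the modified `spec`.
#' @export
applyThinning <- function(spec, factor, side = c("medial", "lateral")) {
  stopifnot(is(spec, "PhantomSpec"), factor > 0, factor <= 1)
  side <- match.arg(side)
  s <- if (side == "medial") 1L else 2L
  newShell <- spec@shellThicknessUm
  newShell[s] <- newShell[s] * factor
  if (newShell[s] < 2 * spec@voxelSizeUm)
    stop("thinning factor produces a shell thinner than 2 voxels")
  spec2 <- spec
  spec2@shellThicknessUm <- newShell
  validObject(spec2)
  geo <- phantomGeometry(spec2)
  vol <- phantomRender(phantomClassGrey(geo$labels, spec2), spec2)
  tf <- c(1, 1)
  tf[s] <- factor
  list(volume = greyVolume(vol, spec2@voxelSizeUm, "raw"),
       truth = makeTruth(geo, spec2, thinningFactor = tf),
       spec = spec2)
}

#' Carve a scalpel cut into a phantom condyle
#'
#' Replaces a rectangular slot of the chosen condyle with background grey
#' along a band of coronal planes, extending from the cartilage surface down
#' `depthUm`; when the depth exceeds the shell the mineralized compartment
#' is perforated too. Truth masks are updated before blur/noise are applied,
#' so segmentation accuracy can be scored against the damaged geometry.
#'
#' @param spec the [PhantomSpec-class] of the intact phantom.
#' @param side condyle to cut, `"medial"` or `"lateral"`.
#' @param positionAPUm AP position of the cut centre, um from the anterior
#'   grid face; `NULL` centres the cut on the condyle apex.
#' @param widthUm AP width of the slot, um.
#' @param depthUm depth of the slot below the local cartilage surface, um;
#'   `0` is the identity.
#' @return list with `volume`, `truth` and `spec`.
#' @export
applyScalpelCut <- function(spec, side = c("medial", "lateral"),
                            positionAPUm = NULL, widthUm = 10,
                            depthUm = 60) {
  stopifnot(is(spec, "PhantomSpec"), widthUm > 0, depthUm >= 0)
  side <- match.arg(side)
  s <- if (side == "medial") 1L else 2L
  geo <- phantomGeometry(spec)
  vox <- spec@voxelSizeUm
  d <- spec@extents
  if (is.null(positionAPUm)) positionAPUm <- geo$centres[s, 1L] * vox
  i0 <- floor((positionAPUm - widthUm / 2) / vox + 0.5)
  i1 <- ceiling((positionAPUm + widthUm / 2) / vox - 0.5)
  if (i1 < i0) i1 <- i0                  # at least one slice
  if (i0 < 0 || i1 > d[1L] - 1) stop("cut outside grid")
  depthVox <- round(depthUm / vox)

  labels <- geo$labels
  cart <- geo$cart
  bone <- geo$bone
  cutHit <- FALSE
  if (depthVox > 0) {
    ## side ownership: nearer to the cut condyle centre than to the other
    for (i in (i0:i1) + 1L) {
      slCart <- cart[i, , ]
      for (k in seq_len(d[3L])) {
        col <- which(slCart[, k])
        if (length(col) == 0L) next
        dML <- (k - 1 - geo$centres[, 3L])^2 + (i - 1 - geo$centres[, 1L])^2
        if (which.min(dML) != s) next
        js <- min(col)
        jr <- js:min(js + depthVox - 1L, d[2L])
        labels[i, jr, k] <- 1L
        cart[i, jr, k] <- FALSE
        bone[i, jr, k] <- FALSE
        cutHit <- TRUE
      }
    }
  }
  if (depthVox > 0 && !cutHit) stop("cut does not lie on a condyle")
  geo$labels <- labels
  geo$cart <- cart
  geo$bone <- bone
  geo$depth[!cart] <- NA_real_
  vol <- phantomRender(phantomClassGrey(labels, spec), spec)
  list(volume = greyVolume(vol, vox, "raw"),
       truth = makeTruth(geo, spec,
                         cutParameters = c(positionAPUm, widthUm, depthUm)),
       spec = spec)
}

## saturating-front stain model: fractional saturation of a cartilage voxel
## at depth d (um) below the surface at time t (h)
uptakeFraction <- function(depthUm, tH, kUptake, surfaceLagHPerUm) {
  pmax(0, 1 - exp(-kUptake * (tH - depthUm * surfaceLagHPerUm)))
}

#' Simulate a stain-uptake image series
#'
#' Cartilage grey at depth `d` below the articular surface and time `t`
#' follows the saturating front
#' `g_bkg + (g_cart - g_bkg) * max(0, 1 - exp(-k * (t - d * lag)))`:
#' staining starts at the surface and propagates inward, so at `t = 0`
#' cartilage is indistinguishable from background (unstained soft tissue is
#' undetectable) and for large `t` it saturates at the full cartilage grey.
#' Mineralized tissue and background are constant in time.
#'
#' @param spec a [PhantomSpec-class]; blur and noise are applied per time
#'   point (noise re-seeded per frame from `spec@seed`).
#' @param timesH strictly increasing acquisition times, hours.
#' @param kUptake saturation rate constant, 1/h.
#' @param surfaceLagHPerUm delay per um of depth before staining starts,
#'   h/um.
#' @return list with `volumes` (list of [GreyVolume-class], one per time),
#'   `timesH`, and the phantom `truth`.
#' @export
simulateUptakeSeries <- function(spec, timesH, kUptake = 2,
                                 surfaceLagHPerUm = 0.005) {
  stopifnot(is(spec, "PhantomSpec"), all(timesH >= 0))
  if (is.unsorted(timesH, strictly = TRUE))
    stop("timesH must be strictly increasing")
  geo <- phantomGeometry(spec)
  base <- phantomClassGrey(geo$labels, spec)
  cartIdx <- which(geo$cart)
  depths <- geo$depth[cartIdx]
  vols <- vector("list", length(timesH))
  for (ti in seq_along(timesH)) {
    g <- base
    frac <- uptakeFraction(depths, timesH[ti], kUptake, surfaceLagHPerUm)
    g[cartIdx] <- spec@greyBkg + (spec@greyCartilage - spec@greyBkg) * frac
    vols[[ti]] <- greyVolume(phantomRender(g, spec, seedOffset = ti),
                             spec@voxelSizeUm, "raw")
  }
  list(volumes = vols, timesH = timesH, truth = makeTruth(geo, spec))
}

#' Model-predicted mean cartilage intensity of an uptake series
#'
#' Evaluates the saturating-front model of [simulateUptakeSeries()] averaged
#' over the phantom's cartilage voxels, without rendering volumes — the
#' closed-form reference curve for plateau-detection checks.
#'
#' @param spec a [PhantomSpec-class].
#' @param timesH times at which to evaluate, hours.
#' @param kUptake,surfaceLagHPerUm model parameters as in
#'   [simulateUptakeSeries()].
#' @return numeric vector of mean cartilage intensities.
#' @export
uptakeMeanAC <- function(spec, timesH, kUptake = 2,
                         surfaceLagHPerUm = 0.005) {
  geo <- phantomGeometry(spec)
  depths <- geo$depth[geo$cart]
  vapply(timesH, function(t) {
    frac <- uptakeFraction(depths, t, kUptake, surfaceLagHPerUm)
    mean(spec@greyBkg + (spec@greyCartilage - spec@greyBkg) * frac)
  }, numeric(1L))
}
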