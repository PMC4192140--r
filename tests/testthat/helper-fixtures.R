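## Shared fixtures and small geometry helpers. Expensive phantom runs are
## cached per session so several test files can reuse them.

diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

## digital ball mask: diameter d voxels (radius (d - 1) / 2 around a centre
## voxel), padded with margin background on every side
makeBallMask <- function(diameter, voxelSizeUm = 5, margin = 3L) {
  r <- (diameter - 1) / 2
  n <- as.integer(diameter + 2 * margin)
  c0 <- margin + (diameter + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  ball <- array((g$i - c0)^2 + (g$j - c0)^2 + (g$k - c0)^2 <= r^2 + 1e-9,
                c(n, n, n))
  voxelMask(ball, voxelSizeUm)
}

## slab of given thickness (voxels) padded laterally so interior voxels see
## an effectively infinite slab
makeSlabMask <- function(thickness, lateral = 40L, voxelSizeUm = 5,
                         margin = 3L) {
  nv <- as.integer(thickness + 2 * margin)
  m <- array(FALSE, c(lateral, nv, lateral))
  m[, margin + seq_len(thickness), ] <- TRUE
  voxelMask(m, voxelSizeUm)
}

## union of random spheres inside a <= 32^3 grid (seeded)
makeRandomBlob <- function(seed, n = 28L) {
  set.seed(seed)
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  b <- array(FALSE, c(n, n, n))
  for (q in seq_len(sample(3:6, 1))) {
    cc <- sample(seq(6L, n - 6L), 3L, replace = TRUE)
    rr <- runif(1, 2.5, 6.5)
    b <- b | array((g$i - cc[1])^2 + (g$j - cc[2])^2 + (g$k - cc[3])^2 <=
                     rr^2, c(n, n, n))
  }
  voxelMask(b, 1)
}

## small tibia phantom spec (fast; used where the full-size geometry is not
## needed)
smallPhantomSpec <- function(...) {
  phantomSpec(extents = c(80L, 60L, 160L), condyleRadiusUm = 120,
              condyleCentresML = c(-200, 200), shellThicknessUm = c(60, 60),
              ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixtureCache)) assign(key, force(expr), .fixtureCache)
  get(key, .fixtureCache)
}

## default-condition phantom run: phantom + segmentation + landmarks + ROIs
## + thickness field + map
fixtureDefaultRun <- function() {
  cached("defaultRun", {
    ph <- makeTibiaPhantom(phantomSpec())
    seg <- segmentCartilage(ph$volume)
    fore <- voxelMask(seg@cartilage@data | seg@mineralized@data,
                      voxelSize(ph$volume), "foreground")
    landmarks <- detectLandmarks(fore)
    rois <- placeCondyleROIs(seg@cartilage, landmarks)
    field <- localThickness(seg@cartilage)
    list(phantom = ph, seg = seg, landmarks = landmarks, rois = rois,
         field = field, map = thicknessMap(field))
  })
}

## noise-free, blur-free default phantom (piecewise-constant greys)
fixtureCleanPhantom <- function() {
  cached("cleanPhantom",
         makeTibiaPhantom(phantomSpec(noiseSd = 0, blurSigmaUm = 0)))
}
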