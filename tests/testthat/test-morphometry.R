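test_that("analytic shapes recover their closed-form thickness", {
  ## digital ball, diameter 21 voxels = 105 um at 5 um voxels
  f <- localThickness(makeBallMask(21, 5))
  v <- voxelData(f)
  expect_lt(max(abs(v / 5 - 21), na.rm = TRUE), 1)
  ## all voxels share the ball's single inscribed sphere
  expect_identical(length(unique(v[!is.na(v)])), 1L)
  ## padded slab of 12 voxels: interior thickness exactly 12
  fs <- localThickness(makeSlabMask(12, voxelSizeUm = 5))
  centre <- voxelData(fs)[20, 8, 20]
  expect_equal(centre / 5, 12)
  expect_error(localThickness(voxelMask(array(FALSE, c(2, 2, 2)), 5)),
               "empty")
})

test_that("ridge-based thickness equals the exhaustive oracle on blobs", {
  for (seed in 1:8) {
    m <- makeRandomBlob(seed)
    a <- voxelData(localThickness(m))
    b <- voxelData(localThicknessBruteForce(m))
    expect_lt(max(abs(a - b), na.rm = TRUE), 1e-9)
  }
})

test_that("thickness is monotone under mask dilation", {
  dilate6 <- function(x) {
    d <- dim(x)
    y <- x
    y[-1, , ] <- y[-1, , ] | x[-d[1], , ]
    y[-d[1], , ] <- y[-d[1], , ] | x[-1, , ]
    y[, -1, ] <- y[, -1, ] | x[, -d[2], ]
    y[, -d[2], ] <- y[, -d[2], ] | x[, -1, ]
    y[, , -1] <- y[, , -1] | x[, , -d[3]]
    y[, , -d[3]] <- y[, , -d[3]] | x[, , -1]
    y
  }
  for (seed in c(3, 9)) {
    m <- makeRandomBlob(seed)
    big <- voxelMask(dilate6(m@data), 1)
    a <- voxelData(localThickness(m))
    b <- voxelData(localThickness(big))
    idx <- !is.na(a)
    expect_true(all(b[idx] >= a[idx] - 1e-9))
  }
})

test_that("ROI volumes are exact voxel counts and additive", {
  m <- voxelMask(array(TRUE, c(170, 90, 110)), 5)
  full <- roiBox(c(5, 5, 5), c(160, 80, 100), "medial")
  expect_equal(roiVolume(m, full), 1.28e6 * 125 * 1e-9)   # 0.16 mm^3
  left <- roiBox(c(5, 5, 5), c(160, 80, 50), "medial")
  right <- roiBox(c(5, 5, 55), c(160, 80, 50), "medial")
  expect_identical(roiVolume(m, left) + roiVolume(m, right),
                   roiVolume(m, full))
  empty <- voxelMask(array(FALSE, c(170, 90, 110)), 5)
  expect_identical(roiVolume(empty, full), 0)
})

test_that("mean thickness recovers the phantom shell and its thinning", {
  run <- fixtureDefaultRun()
  for (s in c("medial", "lateral")) {
    mt <- meanThickness(run$field, run$seg@cartilage, run$rois[[s]])
    expect_lt(abs(mt - 60), 5)
  }
  ## single-voxel box returns that voxel's value
  cartIdx <- which(run$seg@cartilage@data, arr.ind = TRUE)[1000, ]
  one <- roiBox(cartIdx - 1L, c(1L, 1L, 1L), "medial")
  expect_identical(meanThickness(run$field, run$seg@cartilage, one),
                   voxelData(run$field)[cartIdx[1], cartIdx[2], cartIdx[3]])
  expect_error(meanThickness(run$field, run$seg@cartilage,
                             roiBox(c(0, 0, 0), c(2, 2, 2), "medial")),
               "empty")
  ## truth-mask thinning ratio: thinned / control tracks the factor
  spec <- phantomSpec(noiseSd = 0, blurSigmaUm = 0)
  ctrl <- makeTibiaPhantom(spec)
  thin <- applyThinning(spec, 0.85, "medial")
  fc <- localThickness(ctrl$truth@cartilageMask)
  ft <- localThickness(thin$truth@cartilageMask)
  lmk <- detectLandmarks(ctrl$truth@cartilageMask)
  rois <- placeCondyleROIs(ctrl$truth@cartilageMask, lmk)
  ratio <- meanThickness(ft, thin$truth@cartilageMask, rois$medial) /
    meanThickness(fc, ctrl$truth@cartilageMask, rois$medial)
  expect_lt(abs(ratio - 0.85), 0.03)
})

test_that("thickness maps project per column with max >= mean", {
  run <- fixtureDefaultRun()
  mapMax <- run$map
  mapMean <- thicknessMap(run$field, "mean")
  idx <- !is.na(mapMax@grid)
  expect_identical(idx, !is.na(mapMean@grid))
  expect_true(all(mapMax@grid[idx] >= mapMean@grid[idx] - 1e-9))
  ## near-constant over the dome interiors, peaks at the condyle centres
  for (s in c("medial", "lateral")) {
    ctr <- run$phantom$truth@condyleCentres[s, ]
    i <- round(ctr["AP"]) + 1L
    k <- round(ctr["ML"]) + 1L
    expect_lt(abs(mapMax@grid[i, k] - 60), 8)
    ## radial decrease towards the dome rim on the ML profile
    rim <- mapMax@grid[i, k + 48L]
    expect_lt(rim, mapMax@grid[i, k])
  }
})

test_that("profiles cut the map along named lines and average exactly", {
  run <- fixtureDefaultRun()
  prof <- thicknessProfile(run$map, "mediolateral",
                           landmarks = run$landmarks)
  expect_identical(length(prof), ncol(run$map@grid))
  ## symmetric phantom: two equal peaks
  ax <- run$landmarks@symmetryAxisML
  medPeak <- max(prof[seq_len(floor(ax))], na.rm = TRUE)
  latPeak <- max(prof[seq.int(ceiling(ax) + 2, length(prof))], na.rm = TRUE)
  expect_lt(abs(medPeak - latPeak), 5)
  apProf <- thicknessProfile(run$map, "anteroposterior_medial",
                             landmarks = run$landmarks)
  expect_identical(length(apProf), nrow(run$map@grid))
  ## averaging n identical profiles returns the profile
  expect_identical(averageProfiles(list(prof, prof, prof)), prof)
  expect_error(thicknessProfile(run$map, "mediolateral", position = 1e5),
               "outside")
})

test_that("thinned phantoms reduce the medial profile peak by the factor", {
  spec <- phantomSpec(noiseSd = 0, blurSigmaUm = 0)
  ctrl <- makeTibiaPhantom(spec)
  thin <- applyThinning(spec, 0.75, "medial")
  mapC <- thicknessMap(localThickness(ctrl$truth@cartilageMask))
  mapT <- thicknessMap(localThickness(thin$truth@cartilageMask))
  lmk <- detectLandmarks(ctrl$truth@cartilageMask)
  pC <- thicknessProfile(mapC, "mediolateral", landmarks = lmk)
  pT <- thicknessProfile(mapT, "mediolateral", landmarks = lmk)
  ax <- lmk@symmetryAxisML
  medC <- max(pC[seq_len(floor(ax))], na.rm = TRUE)
  medT <- max(pT[seq_len(floor(ax))], na.rm = TRUE)
  expect_lt(abs(medT / medC - 0.75), 0.05)
})
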