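test_that("noise-free phantom is piecewise constant with ordered greys", {
  ph <- fixtureCleanPhantom()
  vals <- sort(unique(as.vector(voxelData(ph$volume))))
  expect_identical(length(vals), 3L)
  sp <- phantomSpec()
  expect_equal(vals, c(sp@greyBkg, sp@greyBone, sp@greyCartilage))
  ## class means in the rendered volume keep the contrast sign structure
  tr <- ph$truth
  v <- voxelData(ph$volume)
  expect_gt(mean(v[tr@cartilageMask@data]), mean(v[tr@boneMask@data]))
  expect_gt(mean(v[tr@boneMask@data]),
            mean(v[!tr@cartilageMask@data & !tr@boneMask@data]))
})

test_that("truth shell is the analytic thickness along the apex normal", {
  ph <- fixtureCleanPhantom()
  tr <- ph$truth
  for (s in c("medial", "lateral")) {
    ctr <- tr@condyleCentres[s, ]
    col <- tr@cartilageMask@data[round(ctr["AP"]) + 1L, ,
                                 round(ctr["ML"]) + 1L]
    expect_identical(sum(col), 12L)   # 60 um / 5 um
    ## contiguous block ending right above the bone dome
    expect_identical(diff(range(which(col))) + 1L, 12L)
  }
})

test_that("phantom generation is a pure seeded function of its spec", {
  a <- makeTibiaPhantom(phantomSpec(seed = 5))
  b <- makeTibiaPhantom(phantomSpec(seed = 5))
  c <- makeTibiaPhantom(phantomSpec(seed = 6))
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_false(identical(voxelData(a$volume), voxelData(c$volume)))
  ## truth is noise-independent
  expect_identical(a$truth@cartilageMask@data, c$truth@cartilageMask@data)
})

test_that("thinning rescales one side's truth shell and records the factor", {
  spec <- smallPhantomSpec(noiseSd = 0, blurSigmaUm = 0)
  base <- makeTibiaPhantom(spec)
  same <- applyThinning(spec, 1, "medial")
  expect_identical(voxelData(same$volume), voxelData(base$volume))
  thin <- applyThinning(spec, 0.5, "medial")
  expect_equal(thin$truth@shellThicknessUm, c(30, 60))
  expect_equal(thin$truth@thinningFactor, c(0.5, 1))
  ## medial apex shell now 6 voxels, lateral unchanged at 12
  ctrM <- thin$truth@condyleCentres["medial", ]
  colM <- thin$truth@cartilageMask@data[round(ctrM["AP"]) + 1L, ,
                                        round(ctrM["ML"]) + 1L]
  expect_identical(sum(colM), 6L)
  ctrL <- thin$truth@condyleCentres["lateral", ]
  colL <- thin$truth@cartilageMask@data[round(ctrL["AP"]) + 1L, ,
                                        round(ctrL["ML"]) + 1L]
  expect_identical(sum(colL), 12L)
  expect_error(applyThinning(spec, 0.1, "medial"), "thinner")
})

test_that("scalpel cuts carve the truth masks exactly where programmed", {
  spec <- smallPhantomSpec(noiseSd = 0, blurSigmaUm = 0)
  base <- makeTibiaPhantom(spec)
  ## depth 0 -> identity
  none <- applyScalpelCut(spec, "medial", widthUm = 10, depthUm = 0)
  expect_identical(voxelData(none$volume), voxelData(base$volume))
  ## shell-deep cut: cartilage slot as programmed; the plateau is nicked
  ## only near the shell rim where the cartilage chord is thinner
  cut <- applyScalpelCut(spec, "medial", widthUm = 10, depthUm = 60)
  removed <- base$truth@cartilageMask@data & !cut$truth@cartilageMask@data
  expect_gt(sum(removed), 0)
  boneLossShallow <- sum(base$truth@boneMask@data) -
    sum(cut$truth@boneMask@data)
  ## slot voxels are confined to the programmed AP band on the medial side
  idx <- which(removed, arr.ind = TRUE)
  pos <- cut$truth@cutParameters[1L] / spec@voxelSizeUm
  expect_true(all(abs(idx[, 1L] - 1 - pos) <= 2))
  expect_true(all(idx[, 3L] - 1 < mean(cut$truth@condyleCentres[, "ML"])))
  ## a deeper cut perforates the mineralized compartment much further
  deep <- applyScalpelCut(spec, "medial", widthUm = 10, depthUm = 120)
  boneLossDeep <- sum(base$truth@boneMask@data) -
    sum(deep$truth@boneMask@data)
  expect_gt(boneLossDeep, boneLossShallow)
  expect_error(applyScalpelCut(spec, "medial", positionAPUm = 1e6,
                               widthUm = 10, depthUm = 60), "outside")
})

test_that("uptake simulation starts at background and saturates monotonically", {
  spec <- smallPhantomSpec(noiseSd = 0, blurSigmaUm = 0)
  times <- c(0, 0.5, 1.5, 4, 24)
  sim <- simulateUptakeSeries(spec, times, kUptake = 2,
                              surfaceLagHPerUm = 0.005)
  cart <- sim$truth@cartilageMask@data
  v0 <- voxelData(sim$volumes[[1L]])
  expect_true(all(v0[cart] == spec@greyBkg))
  vEnd <- voxelData(sim$volumes[[length(times)]])
  expect_equal(max(abs(vEnd[cart] - spec@greyCartilage)), 0,
               tolerance = 1e-6)
  ## closed-form mean curve equals the rendered means and is non-decreasing
  means <- vapply(sim$volumes, function(v) mean(voxelData(v)[cart]),
                  numeric(1))
  expect_equal(means, uptakeMeanAC(spec, times, 2, 0.005), tolerance = 1e-9)
  expect_true(all(diff(means) >= 0))
  ## mineralized and background intensities constant over time
  bone <- sim$truth@boneMask@data
  expect_identical(voxelData(sim$volumes[[1L]])[bone],
                   voxelData(sim$volumes[[5L]])[bone])
  expect_error(simulateUptakeSeries(spec, c(1, 0.5)), "increasing")
})

test_that("overlapping or oversized condyles are rejected", {
  expect_error(makeTibiaPhantom(phantomSpec(condyleCentresML = c(-100, 100))),
               "overlapping")
  expect_error(makeTibiaPhantom(phantomSpec(extents = c(180L, 30L, 280L))),
               "exceed")
  expect_error(phantomSpec(greyBone = 300), "grey levels")
  expect_error(phantomSpec(shellThicknessUm = c(5, 60)), "shell")
})
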