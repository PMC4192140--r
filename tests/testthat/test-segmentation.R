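## reference histograms built directly from counts
histFromCounts <- function(counts, lo = 0) {
  mids <- seq(lo, lo + length(counts) - 1)
  structure(list(edges = c(mids - 0.5, mids[length(mids)] + 0.5),
                 mids = mids, counts = counts),
            class = "greyHistogram")
}

test_that("Otsu separates a perfect bimodal histogram between the modes", {
  counts <- integer(256)
  counts[10 + 1] <- 500
  counts[200 + 1] <- 300
  t <- otsuThreshold(histFromCounts(counts))
  expect_gt(t, 10)
  expect_lte(t, 200)
})

test_that("Otsu equals the exhaustive intra-class-variance minimiser", {
  set.seed(101)
  for (r in 1:150) {
    counts <- rpois(256, sample(1:40, 1)) +
      ifelse(runif(256) < 0.02, sample(200:2000, 256, TRUE), 0)
    if (sum(counts > 0) < 3) next
    h <- histFromCounts(counts)
    expect_identical(otsuThreshold(h), otsuBruteForce(h, 2L))
    expect_identical(multiOtsu(h, 3L), otsuBruteForce(h, 3L))
  }
})

test_that("symmetric bimodal mixtures threshold at the midpoint bin", {
  counts <- integer(101)
  x <- 0:100
  counts <- round(400 * exp(-(x - 25)^2 / 288) + 400 * exp(-(x - 75)^2 / 288))
  h <- histFromCounts(counts)
  t <- otsuThreshold(h)
  expect_equal(otsuBruteForce(h, 2L), t)
  expect_lt(abs(t - 50), 1.5)
})

test_that("three delta peaks are isolated by two thresholds", {
  counts <- integer(256)
  counts[c(10, 120, 200) + 1] <- c(400, 300, 350)
  th <- multiOtsu(histFromCounts(counts), 3L)
  expect_identical(length(th), 2L)
  expect_true(th[1] > 10 && th[1] <= 120)
  expect_true(th[2] > 120 && th[2] <= 200)
  ## classes = 2 reduces to the plain threshold
  h2 <- histFromCounts(counts)
  expect_identical(multiOtsu(h2, 2L), otsuThreshold(h2))
  expect_error(otsuThreshold(histFromCounts(c(0L, 7L, 0L))), "non-empty")
})

test_that("noise-free phantom segments to the exact truth masks", {
  ph <- fixtureCleanPhantom()
  seg <- segmentCartilage(ph$volume)
  expect_identical(seg@cartilage@data, ph$truth@cartilageMask@data)
  expect_identical(seg@mineralized@data, ph$truth@boneMask@data)
  expect_identical(length(seg@thresholds), 2L)
})

test_that("segmentation accuracy degrades gracefully with noise", {
  sep <- 185 / 1.35 - 100        # smallest adjacent class separation
  dices <- vapply(c(0, 0.05, 0.10), function(fr) {
    ph <- makeTibiaPhantom(smallPhantomSpec(noiseSd = fr * sep, seed = 21))
    seg <- segmentCartilage(ph$volume)
    diceCoefficient(seg@cartilage@data, ph$truth@cartilageMask@data)
  }, numeric(1))
  ## non-increasing in noise, up to seed-level boundary fluctuation
  expect_true(all(diff(dices) <= 1e-3))
  expect_gte(dices[3], 0.95)
})

test_that("segmentation is invariant to a constant intensity shift", {
  ph <- makeTibiaPhantom(smallPhantomSpec(seed = 4))
  seg1 <- segmentCartilage(ph$volume)
  shifted <- greyVolume(voxelData(ph$volume) + 57.3, voxelSize(ph$volume))
  seg2 <- segmentCartilage(shifted)
  expect_identical(seg1@cartilage@data, seg2@cartilage@data)
  expect_identical(seg1@mineralized@data, seg2@mineralized@data)
})

test_that("otsu2 mode extracts the brightest layer hierarchically", {
  ph <- fixtureCleanPhantom()
  seg <- segmentCartilage(ph$volume, method = "otsu2")
  expect_identical(seg@method, "otsu2")
  expect_gte(diceCoefficient(seg@cartilage@data,
                             ph$truth@cartilageMask@data), 0.99)
})

test_that("line profiles locate the surface and tidemark transitions", {
  ph <- fixtureCleanPhantom()
  seg <- segmentCartilage(ph$volume)
  tr <- ph$truth
  ctr <- tr@condyleCentres["medial", ]
  i <- round(ctr["AP"]) + 1L
  k <- round(ctr["ML"]) + 1L
  bp <- boundaryProfile(ph$volume, c(i, 1, k), c(i, 90, k), seg@thresholds)
  ## expected 0-based rows from the analytic geometry
  spec <- phantomSpec(noiseSd = 0, blurSigmaUm = 0)
  vox <- spec@voxelSizeUm
  surfaceRow <- ctr["vert"] - (spec@condyleRadiusUm + 60) / vox
  tidemarkRow <- ctr["vert"] - spec@condyleRadiusUm / vox
  up <- bp$transitions[bp$transitions$from == 1 & bp$transitions$to == 3, ]
  expect_identical(nrow(up), 1L)                     # one BKG->AC crossing
  ## positions are distances from row 1 (0-based row 0)
  expect_lt(abs(up$position[1] - surfaceRow), 1.5)
  dn <- bp$transitions[bp$transitions$from == 3 & bp$transitions$to == 2, ]
  expect_lt(abs(dn$position[1] - tidemarkRow), 1.5)
  ## background-only line: no transitions
  flat <- boundaryProfile(ph$volume, c(2, 2, 2), c(2, 2, 40),
                          seg@thresholds)
  expect_identical(nrow(flat$transitions), 0L)
  ## sampling contract: ceil(length) samples
  len <- sqrt(sum((c(2, 2, 40) - c(2, 2, 2))^2))
  expect_identical(length(flat$intensity), as.integer(ceiling(len)))
  expect_error(boundaryProfile(ph$volume, c(1, 1, 1), c(1, 1, 1),
                               seg@thresholds), "degenerate")
})
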