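test_that("region means are arithmetic means over masks and boxes", {
  v <- greyVolume(array(7, c(4, 4, 4)), 5)
  expect_identical(regionMean(v, roiBox(c(0, 0, 0), c(4, 4, 4), "medial")),
                   7)
  two <- greyVolume(array(c(100, 200, rep(0, 62)), c(4, 4, 4)), 5)
  m <- array(FALSE, c(4, 4, 4))
  m[1:2, 1, 1] <- TRUE
  expect_identical(regionMean(two, voxelMask(m, 5)), 150)
  expect_error(regionMean(v, voxelMask(array(FALSE, c(4, 4, 4)), 5)),
               "empty")
  ## noisy phantom: cartilage mean within a CLT band of the class grey
  spec <- smallPhantomSpec(blurSigmaUm = 0, seed = 31)
  ph <- makeTibiaPhantom(spec)
  cart <- ph$truth@cartilageMask
  n <- sum(cart@data)
  got <- regionMean(ph$volume, cart)
  expect_lt(abs(got - spec@greyCartilage), 4 * spec@noiseSd / sqrt(n))
})

test_that("SBR is the relative percent contrast with its invariances", {
  expect_identical(sbr(185, 100), 85)
  expect_identical(sbr(135, 100), 35)
  expect_identical(sbr(100, 100), 0)
  expect_error(sbr(10, 0), "positive")
  ## scale invariance and monotonicity
  expect_equal(sbr(370, 200), sbr(185, 100))
  expect_true(sbr(140, 100) > sbr(135, 100))
})

test_that("uptake time courses track the simulation model", {
  spec <- smallPhantomSpec(noiseSd = 0, blurSigmaUm = 0)
  times <- c(0, 0.5, 1, 1.5, 2, 3, 4.5, 8, 24)
  sim <- simulateUptakeSeries(spec, times, kUptake = 2,
                              surfaceLagHPerUm = 0.005)
  us <- uptakeTimecourse(sim$volumes, times, sim$truth@cartilageMask,
                         roiBox(c(5, 2, 5), c(20, 6, 20), "medial"),
                         sim$truth@boneMask)
  expect_true(all(diff(us@meanAC) >= -1e-9))
  expect_true(all(us@meanBKG == us@meanBKG[1]))       # constant in time
  expect_true(all(us@meanSCP == us@meanSCP[1]))
  expect_equal(us@sbrAcBkg[length(times)], 85, tolerance = 1e-6)
  expect_equal(us@sbrAcScp[length(times)], 35, tolerance = 1e-6)
  ## single time point: a length-1 series, no plateau estimate possible
  one <- uptakeTimecourse(sim$volumes[1], times[1],
                          sim$truth@cartilageMask,
                          roiBox(c(5, 2, 5), c(20, 6, 20), "medial"),
                          sim$truth@boneMask)
  expect_identical(length(one@timesH), 1L)
  expect_error(detectPlateau(one), "3 time points")
  ## mismatched grids are rejected
  other <- greyVolume(array(0, c(2, 2, 2)), 5)
  expect_error(uptakeTimecourse(list(sim$volumes[[1]], other), c(0, 1),
                                sim$truth@cartilageMask,
                                roiBox(c(0, 0, 0), c(2, 2, 2), "medial"),
                                sim$truth@boneMask), "mismatched")
})

test_that("plateau detection follows its band contract", {
  mkSeries <- function(ac) {
    n <- length(ac)
    new("UptakeSeries", timesH = as.numeric(seq_len(n)), meanAC = ac,
        meanBKG = rep(1, n), meanSCP = rep(1, n),
        sbrAcBkg = rep(0, n), sbrAcScp = rep(0, n))
  }
  expect_identical(detectPlateau(mkSeries(rep(5, 6)), 0.05), 1)
  ## saturation between samples 3 and 4 -> plateau reported at sample 4
  ac <- c(10, 60, 93, 99, 99.7, 100)
  expect_identical(detectPlateau(mkSeries(ac), 0.02), 4)
  ## strictly increasing unsaturated series, tight tolerance -> error
  expect_error(detectPlateau(mkSeries(c(1, 2, 4, 8, 16, 32)), 0.01),
               "never enters")
})

test_that("detected plateau converges to the analytic saturation time", {
  spec <- smallPhantomSpec(noiseSd = 0, blurSigmaUm = 0)
  k <- 2
  lag <- 0.005
  tol <- 0.02
  tEnd <- 24
  ## analytic band-crossing time of the closed-form mean curve
  target <- uptakeMeanAC(spec, tEnd, k, lag)
  crossing <- stats::uniroot(function(t)
    uptakeMeanAC(spec, t, k, lag) - (1 - tol) * target,
    c(0.01, tEnd))$root
  for (nSamp in c(9, 17)) {
    times <- c(seq(0, 4, length.out = nSamp), tEnd)
    sim <- simulateUptakeSeries(spec, times, k, lag)
    us <- uptakeTimecourse(sim$volumes, times, sim$truth@cartilageMask,
                           roiBox(c(5, 2, 5), c(20, 6, 20), "medial"),
                           sim$truth@boneMask)
    plateau <- detectPlateau(us, tol)
    dt <- max(diff(times[times <= 5]))
    expect_lt(abs(plateau - crossing), dt + 1e-9)
  }
})
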