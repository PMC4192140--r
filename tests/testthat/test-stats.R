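## sign-pattern enumeration oracle for the Wilcoxon signed-rank test:
## exact two-sided p of observing a rank sum at least as extreme as W
## under random signs
wilcoxonEnumeration <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  sums <- vapply(seq_len(2^n) - 1L, function(bits) {
    signs <- bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0
    sum(rk[signs])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(sums >= W), mean(sums <= W)))
}

test_that("paired t matches its closed form and symmetry", {
  b <- c(10, 20, 30)
  a <- b + c(1, 2, 3)
  r <- pairedT(a, b)
  expect_equal(r@statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(r@dof, 2)
  expect_equal(r@pValue, 2 * stats::pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  ## identical samples: t = 0, p = 1 by convention
  same <- pairedT(b, b)
  expect_identical(same@statistic, 0)
  expect_identical(same@pValue, 1)
  ## swapping the arms negates t, leaves p
  sw <- pairedT(b, a)
  expect_equal(sw@statistic, -r@statistic)
  expect_equal(sw@pValue, r@pValue)
  expect_error(pairedT(b + 5, b), "undefined")
})

test_that("unpaired t uses pooled variance by default, Welch on request", {
  set.seed(2)
  x <- rnorm(8)
  y <- rnorm(6, 1)
  p <- unpairedT(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(p@statistic, unname(ref$statistic))
  expect_identical(p@dof, 12)
  w <- unpairedT(x, y, welch = TRUE)
  expect_equal(w@dof, unname(stats::t.test(x, y)$parameter))
})

test_that("Wilcoxon signed-rank matches full sign-pattern enumeration", {
  ## five all-positive differences: W = 15, two-sided p = 1/16
  b <- c(1, 2, 3, 4, 5)
  a <- b + c(0.5, 1.2, 0.7, 2.1, 1.9)
  r <- wilcoxonSignedRank(a, b)
  expect_identical(unname(r@statistic), 15)
  expect_equal(r@pValue, 1 / 16, tolerance = 1e-12)
  expect_equal(wilcoxonEnumeration(a - b), 1 / 16, tolerance = 1e-12)
  ## enumeration oracle on mixed-sign integer samples
  for (d in list(c(3, -1, 4, 2, -6, 5), c(2, -3, 1.5, 7, -0.5, 4, 6, -8))) {
    got <- wilcoxonSignedRank(d, rep(0, length(d)))@pValue
    expect_equal(got, wilcoxonEnumeration(d), tolerance = 1e-12)
  }
  ## sign flip leaves the two-sided p unchanged
  expect_equal(wilcoxonSignedRank(b, a)@pValue, r@pValue)
  expect_error(wilcoxonSignedRank(b, b), "zero")
})

test_that("KS normality check behaves on known samples", {
  set.seed(77)
  x <- rnorm(500)
  r <- ksNormality(x)
  expect_gt(r@pValue, 0.05)
  expect_true(r@statistic >= 0 && r@statistic <= 1)
  u <- runif(500)
  expect_gt(ksNormality(u)@statistic, r@statistic)
  expect_error(ksNormality(rep(1, 5)), "degenerate")
})

test_that("regression reports slope, r2 and slope p-value", {
  x <- seq(1, 10, length.out = 20)
  fit <- suppressWarnings(regressionR2(x, 2 * x + 1))  # exact fit warns
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  set.seed(5)
  noise <- regressionR2(seq_len(100), rnorm(100))
  expect_lt(noise$r2, 0.05)
  ## r2 invariant to affine rescaling of either variable
  y <- 3 * x + rnorm(20, sd = 2)
  expect_equal(regressionR2(x, y)$r2,
               regressionR2(10 * x - 4, 0.1 * y + 7)$r2, tolerance = 1e-12)
  expect_equal(regressionR2(x, y)$r2, stats::cor(x, y)^2,
               tolerance = 1e-12)
  expect_error(regressionR2(rep(1, 5), 1:5), "constant")
})

test_that("CV and percent difference follow their conventions", {
  expect_identical(coefficientOfVariation(c(10, 10, 10)), 0)
  expect_equal(coefficientOfVariation(c(9, 10, 11)), 10)
  x <- c(4, 7, 9.5)
  expect_equal(coefficientOfVariation(3.7 * x), coefficientOfVariation(x))
  expect_error(coefficientOfVariation(c(-1, 1)), "zero mean")
  expect_identical(percentDifference(50, 50), 0)
  expect_equal(percentDifference(85.2, 100), -14.8)
  ## asymmetric by construction
  expect_false(isTRUE(all.equal(percentDifference(80, 100),
                                -percentDifference(100, 80))))
  expect_error(percentDifference(1, 0), "zero control")
})

test_that("group reports summarise paired arms deterministically", {
  df <- data.frame(
    pair = rep(c("m1", "m2", "m3", "m4"), times = 4),
    group = "4wk",
    side = rep(c("medial", "lateral"), each = 8),
    arm = rep(rep(c("treated", "control"), each = 4), times = 2),
    mean_thickness_um = c(51, 49, 50.5, 48, 60, 59, 61, 60.5,
                          59.5, 60.2, 60.8, 59.9, 60, 59.8, 60.6, 60.1),
    volume_mm3 = runif(16, 0.02, 0.03))
  rep1 <- buildReport(df)
  expect_identical(nrow(rep1), 4L)                 # 2 sides x 2 metrics
  med <- rep1[rep1$side == "medial" &
                rep1$metric == "mean_thickness_um", ]
  expect_lt(med$percent_difference, -10)
  expect_lt(med$p_paired_t, 0.05)
  lat <- rep1[rep1$side == "lateral" &
                rep1$metric == "mean_thickness_um", ]
  expect_lt(abs(lat$percent_difference), 2)
  ## identical arms: zero differences, p = 1
  df2 <- df
  df2$mean_thickness_um <- rep(c(50, 51, 52, 53), times = 4)
  df2$volume_mm3 <- 0.02
  rep2 <- buildReport(df2)
  expect_true(all(rep2$percent_difference == 0))
  expect_true(all(rep2$p_paired_t == 1))
  ## deterministic re-run
  expect_identical(buildReport(df), rep1)
  ## mismatched pairing is an error
  bad <- df[-1, ]
  expect_error(buildReport(bad), "mismatch")
})
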