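testResult <- function(statistic, pValue, dof, ci95, testName) {
  new("TestResult", statistic = as.numeric(statistic),
      pValue = as.numeric(pValue), dof = as.numeric(dof),
      ci95 = as.numeric(ci95), testName = testName)
}

#' Paired two-tailed Student's t test
#'
#' Two-tailed paired t test on index-matched samples (operated vs
#' contralateral control), with the 95% confidence interval of the mean
#' difference. Identical samples (all differences zero) return t = 0,
#' p = 1 by convention; zero variance around a non-zero difference is an
#' error (the statistic is undefined).
#'
#' @param a,b equal-length numeric vectors, paired by index, n >= 2.
#' @return a [TestResult-class].
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(testResult(0, 1, length(d) - 1, c(0, 0), "paired t"))
    stop("zero variance with non-zero difference: t undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  testResult(unname(tt$statistic), tt$p.value, unname(tt$parameter),
             as.numeric(tt$conf.int), "paired t")
}

#' Unpaired two-tailed Student's t test
#'
#' Defaults to the pooled-variance (equal-variance) form; set
#' `welch = TRUE` for the Welch correction.
#'
#' @param x,y numeric vectors, n >= 2 each.
#' @param welch use the Welch (unequal-variance) form.
#' @return a [TestResult-class].
#' @export
unpairedT <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  tt <- stats::t.test(x, y, var.equal = !welch)
  testResult(unname(tt$statistic), tt$p.value, unname(tt$parameter),
             as.numeric(tt$conf.int),
             if (welch) "Welch t" else "unpaired t (pooled)")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the classical convention). The exact null
#' distribution is used for up to 25 non-zero differences without ties;
#' larger or tied samples use the normal approximation with continuity and
#' tie correction.
#'
#' @param a,b equal-length numeric vectors, paired by index.
#' @return a [TestResult-class] (statistic = signed-rank sum V).
#' @export
wilcoxonSignedRank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- (a - b)[a - b != 0]
  if (length(d) == 0L) stop("all differences zero: test undefined")
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = exact, correct = TRUE))
  testResult(unname(wt$statistic), wt$p.value, NA_real_,
             c(NA_real_, NA_real_), "Wilcoxon signed-rank")
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the data against a normal distribution with
#' the sample mean and SD (parameters estimated from the same data, as is
#' common practice for a pre-test of near-normality; this makes the test
#' conservative, which is accepted and documented rather than corrected).
#'
#' @param x numeric vector, n >= 3.
#' @return a [TestResult-class].
#' @export
ksNormality <- function(x) {
  stopifnot(length(x) >= 3L)
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  testResult(unname(kt$statistic), kt$p.value, NA_real_,
             c(NA_real_, NA_real_), "Kolmogorov-Smirnov (normal)")
}

#' Linear regression with Pearson correlation
#'
#' Least-squares fit of `y` on `x`; the coefficient of determination
#' equals the squared Pearson correlation, and the p-value is the
#' two-tailed test of the slope.
#'
#' @param x,y numeric vectors, n >= 3, `x` not constant.
#' @return list with `slope`, `intercept`, `r2`, `p`.
#' @export
regressionR2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("x is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]))
}

#' Coefficient of variation
#'
#' `100 * SD / mean` with the sample (n - 1) standard deviation — the
#' reproducibility metric for repeated scans of the same sample.
#'
#' @param x numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
coefficientOfVariation <- function(x) {
  if (mean(x) == 0) stop("zero mean: CV undefined")
  100 * stats::sd(x) / mean(x)
}

#' Percent difference between treated and control means
#'
#' `100 * (mean_treated - mean_control) / mean_control` — the convention
#' used for operated-vs-contralateral comparisons. Asymmetric by
#' construction: swapping the roles does not merely flip the sign.
#'
#' @param meanTreated,meanControl group means; control must be non-zero.
#' @return percent difference.
#' @export
percentDifference <- function(meanTreated, meanControl) {
  if (any(meanControl == 0)) stop("zero control mean")
  100 * (meanTreated - meanControl) / meanControl
}

#' Build a group comparison report
#'
#' Summarises paired treated-vs-control measurements per group, side and
#' metric: arm means with 95% confidence intervals, the percent difference
#' between the arm means, and the paired two-tailed t p-value. Rows are
#' ordered deterministically (group, side, metric), so re-running on the
#' same input reproduces the report byte for byte.
#'
#' @param df data.frame with columns `pair` (sample identifier), `group`,
#'   `side`, `arm` (`"treated"` or `"control"`), plus one column per
#'   metric.
#' @param metrics names of the metric columns to summarise.
#' @return data.frame with one row per (group, side, metric).
#' @export
buildReport <- function(df, metrics = c("mean_thickness_um",
                                        "volume_mm3")) {
  needed <- c("pair", "group", "side", "arm")
  if (!all(needed %in% names(df)))
    stop("df must have columns: ", paste(needed, collapse = ", "))
  if (!all(metrics %in% names(df)))
    stop("missing metric columns: ",
         paste(setdiff(metrics, names(df)), collapse = ", "))
  ci <- function(x) {
    if (length(x) < 2L) return(c(NA_real_, NA_real_))
    se <- stats::sd(x) / sqrt(length(x))
    mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1L) * se
  }
  rows <- list()
  for (g in sort(unique(as.character(df$group))))
    for (s in sort(unique(as.character(df$side))))
      for (metric in metrics) {
        sub <- df[df$group == g & df$side == s, ]
        if (nrow(sub) == 0L) next
        tr <- sub[sub$arm == "treated", ]
        co <- sub[sub$arm == "control", ]
        tr <- tr[order(tr$pair), ]
        co <- co[order(co$pair), ]
        if (nrow(tr) != nrow(co) || !identical(tr$pair, co$pair))
          stop("group ", g, "/", s, ": treated and control pairs mismatch")
        a <- tr[[metric]]
        b <- co[[metric]]
        tt <- pairedT(a, b)
        ciT <- ci(a)
        ciC <- ci(b)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, side = s, metric = metric, n_pairs = length(a),
          mean_treated = mean(a), ci_lo_treated = ciT[1L],
          ci_hi_treated = ciT[2L],
          mean_control = mean(b), ci_lo_control = ciC[1L],
          ci_hi_control = ciC[2L],
          percent_difference = percentDifference(mean(a), mean(b)),
          p_paired_t = tt@pValue)
      }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
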