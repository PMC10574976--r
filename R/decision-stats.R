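## The decision module: advisory chi-square normality check, pooled-variance
## two-sample Student's t-test between the two partition vectors, and the
## threshold + mean-ordering rule producing the binary adequate/inadequate
## output.

#' Chi-square goodness-of-fit test for normality
#'
#' Bins the sample into `k = max(4, ceiling(sqrt(L)))` equal-probability bins
#' of a normal distribution with mean and standard deviation estimated from
#' the sample, and compares observed with expected counts on `k - 3` degrees
#' of freedom (two estimated parameters plus the count constraint). The check
#' is advisory: a rejection is logged as a warning on the test result, it
#' never blocks the t-test.
#'
#' @param v numeric vector, length at least 8.
#' @return the chi-square p-value; 0 (with a warning) for a zero-variance
#'   sample, for which normality is untestable and trivially violated.
#' @export
chi2Normality <- function(v) {
  n <- length(v)
  if (n < 8L) stop("chi2Normality needs at least 8 values")
  s <- stats::sd(v)
  if (s == 0) {
    warning("zero sample variance: chi-square normality check degenerate")
    return(0)
  }
  k <- max(4L, ceiling(sqrt(n)))
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1L), mean = mean(v), sd = s)
  obs <- tabulate(findInterval(v, breaks[-c(1L, k + 1L)]) + 1L, nbins = k)
  expd <- n / k
  chi2 <- sum((obs - expd)^2 / expd)
  stats::pchisq(chi2, df = k - 3L, lower.tail = FALSE)
}

#' Pooled-variance two-sample Student's t-test
#'
#' The classic equal-variance two-sample t between the two partition vectors:
#' `t = (m1 - m2) / (sp * sqrt(2/L))` with the pooled standard deviation
#' `sp`, and a two-sided p-value from the t distribution on `2L - 2` degrees
#' of freedom. The test is two-sided; directionality (the thrust region must
#' be the *warmer* one) is applied separately by [classify()] through the
#' recorded group means.
#'
#' Degenerate inputs are kept well-defined: two identical constant vectors
#' give t = 0, p = 1 (no evidence of a difference); zero pooled variance with
#' unequal means gives p = 0 with a warning flag (infinitely strong, but
#' suspicious, evidence).
#'
#' @param v1,v2 [PartitionVector-class] objects (or bare numeric vectors) of
#'   equal length L >= 2; `v1` is ROI #1 (thrust), `v2` ROI #2 (reference).
#' @param checkNormality logical; when `TRUE` (default) an advisory
#'   [chi2Normality()] p-value is recorded for each vector if L >= 8.
#' @return a [TestResult-class].
#' @examples
#' studentTTest(1:5, 2:6)   # t = -1, df = 8
#' @export
studentTTest <- function(v1, v2, checkNormality = TRUE) {
  x <- if (is(v1, "PartitionVector")) partMeans(v1) else as.numeric(v1)
  y <- if (is(v2, "PartitionVector")) partMeans(v2) else as.numeric(v2)
  L <- length(x)
  if (length(y) != L) stop("partition vectors must have equal length")
  if (L < 2L) stop("need at least 2 values per vector")
  m1 <- mean(x); m2 <- mean(y)
  df <- 2L * L - 2L
  sp2 <- (stats::var(x) + stats::var(y)) / 2
  warn <- character()
  if (sp2 == 0) {
    if (m1 == m2) { tstat <- 0; p <- 1 }
    else {
      tstat <- sign(m1 - m2) * Inf; p <- 0
      warn <- c(warn, "degenerate: zero pooled variance with unequal means")
    }
  } else {
    tstat <- (m1 - m2) / sqrt(sp2 * 2 / L)
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  np1 <- np2 <- NA_real_
  if (checkNormality && L >= 8L && sp2 > 0) {
    np1 <- suppressWarnings(chi2Normality(x))
    np2 <- suppressWarnings(chi2Normality(y))
    if (min(np1, np2) < 0.05)
      warn <- c(warn, sprintf(
        "chi-square normality check rejected (p1 = %.3g, p2 = %.3g)",
        np1, np2))
  }
  new("TestResult", tStat = tstat, df = df, pValue = p,
      mean1 = m1, mean2 = m2, normalityP1 = np1, normalityP2 = np2,
      warnings = warn)
}

#' Apply the threshold and mean-ordering decision rule
#'
#' Output is 1 (adequate pressure) exactly when the p-value is strictly below
#' the threshold *and* the thrust region mean exceeds the reference mean;
#' otherwise 0 (inadequate). `p == threshold` classifies as inadequate, and a
#' significantly *colder* thrust region also classifies as inadequate — a
#' significant difference in the wrong direction cannot indicate adequate
#' pressure.
#'
#' @param test a [TestResult-class].
#' @param threshold decision threshold in (0, 1); default 0.05.
#' @return an [AssessmentResult-class].
#' @export
classify <- function(test, threshold = 0.05) {
  out <- as.integer(test@pValue < threshold && test@mean1 > test@mean2)
  new("AssessmentResult", test = test, threshold = threshold, output = out)
}

#' Assess one ROI pair on a thermal frame
#'
#' The thermal-grid half of the pipeline: extract the two ROIs, jointly
#' normalise to grayscale, partition, average, t-test, classify. Both
#' rectangles must be in thermal-frame coordinates.
#'
#' @param frame a [ThermalFrame-class].
#' @param roi1,roi2 thermal-frame [Rect-class] rectangles (thrust region and
#'   mirror reference).
#' @param nRows,nCols partition counts (default 4 x 4).
#' @param threshold decision threshold (default 0.05).
#' @return an [AssessmentResult-class].
#' @export
assessRois <- function(frame, roi1, roi2, nRows = 4, nCols = 4,
                       threshold = 0.05) {
  a <- extractRoi(frame, roi1)
  b <- extractRoi(frame, roi2)
  pv <- partitionPair(a, b, nRows, nCols)
  classify(studentTTest(pv[[1]], pv[[2]]), threshold)
}

#' Assess an image pair end to end
#'
#' Full composition of the method for one registered image pair and one
#' operator-selected ROI pair in RGB coordinates: mirror (already encoded in
#' the [RoiPair-class]), map both rectangles onto the thermal grid, extract,
#' jointly normalise, partition into N x M subregions, average, run the
#' pooled t-test and apply the decision rule. Deterministic.
#'
#' @param pair an [ImagePair-class].
#' @param rois a [RoiPair-class] in RGB coordinates.
#' @param nRows,nCols partition counts (default 4 x 4).
#' @param threshold decision threshold (default 0.05).
#' @return an [AssessmentResult-class].
#' @export
assessPair <- function(pair, rois, nRows = 4, nCols = 4, threshold = 0.05) {
  m <- .mapPairToThermal(rois, pair)
  assessRois(pair@thermal, m$roi1, m$roi2, nRows, nCols, threshold)
}

#' Serialise an assessment to a JSON report
#'
#' @param result an [AssessmentResult-class].
#' @param rois the [RoiPair-class] assessed (optional, recorded when given).
#' @param nRows,nCols partition counts used.
#' @param path output path; when `NULL` the JSON string is returned instead.
#' @return `path` (or the JSON string), invisibly.
#' @export
writeAssessment <- function(result, rois = NULL, nRows = 4, nCols = 4,
                            path = NULL) {
  t <- result@test
  rep <- list(
    n_rows = nRows, n_cols = nCols,
    t_stat = t@tStat, df = t@df, p_value = t@pValue,
    mean1 = t@mean1, mean2 = t@mean2,
    normality_p1 = t@normalityP1, normality_p2 = t@normalityP2,
    threshold = result@threshold, output = result@output,
    warnings = as.list(t@warnings))
  if (!is.null(rois))
    rep$rois <- list(
      roi1 = list(x0 = rois@roi1@x0, y0 = rois@roi1@y0,
                  w = rois@roi1@w, h = rois@roi1@h),
      roi2 = list(x0 = rois@roi2@x0, y0 = rois@roi2@y0,
                  w = rois@roi2@w, h = rois@roi2@h),
      axis_x = rois@axisX, frame = rois@roi1@frame)
  if (is.null(path))
    return(invisible(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                      na = "null")))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
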