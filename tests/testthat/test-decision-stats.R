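test_that("pooled t-test matches the hand-computed worked example", {
  # groups (1..5) and (2..6): s^2 = 2.5 each, pooled sd 1.5811, se = 1.0
  r <- studentTTest(1:5, 2:6)
  expect_equal(r@tStat, -1.0, tolerance = 1e-12)
  expect_equal(r@df, 8L)
  expect_equal(r@pValue, 2 * pt(-1, 8), tolerance = 1e-12)
  expect_equal(c(r@mean1, r@mean2), c(3, 4))
})

test_that("pooled t-test agrees with stats::t.test on random vector pairs", {
  set.seed(1234)
  for (i in 1:100) {
    L <- sample(3:40, 1)
    x <- rnorm(L, mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    y <- rnorm(L, mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    ref <- t.test(x, y, var.equal = TRUE)
    mine <- studentTTest(x, y, checkNormality = FALSE)
    expect_lt(abs(mine@pValue - ref$p.value), 1e-9)
    expect_lt(abs(mine@tStat - unname(ref$statistic)), 1e-9)
    expect_equal(mine@df, as.integer(ref$parameter))
  }
})

test_that("t-test is antisymmetric and degenerate inputs stay defined", {
  set.seed(9)
  x <- runif(16); y <- runif(16)
  ab <- studentTTest(x, y, checkNormality = FALSE)
  ba <- studentTTest(y, x, checkNormality = FALSE)
  expect_equal(ab@tStat, -ba@tStat)
  expect_equal(ab@pValue, ba@pValue)

  same <- studentTTest(x, x, checkNormality = FALSE)
  expect_equal(same@tStat, 0)
  expect_equal(same@pValue, 1)

  # identical constant vectors: no evidence
  flat <- studentTTest(rep(0.5, 16), rep(0.5, 16), checkNormality = FALSE)
  expect_equal(c(flat@tStat, flat@pValue), c(0, 1))

  # zero pooled variance with unequal means: degenerate, flagged
  deg <- studentTTest(rep(0.7, 16), rep(0.3, 16), checkNormality = FALSE)
  expect_equal(deg@pValue, 0)
  expect_match(deg@warnings, "degenerate", all = FALSE)
})

test_that("chi-square normality accepts normal and rejects uniform samples", {
  set.seed(77)
  expect_gt(chi2Normality(rnorm(200)), 0.05)

  # power check: scaled-up uniform samples rejected in >= 80% of seeds
  rejections <- vapply(1:100, function(s) {
    set.seed(s)
    chi2Normality(runif(200) * 100) < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)

  expect_warning(p0 <- chi2Normality(rep(1, 20)), "zero sample variance")
  expect_equal(p0, 0)

  # agrees with an independent binning of the same equal-probability breaks
  set.seed(42)
  v <- rnorm(150, 5, 2)
  k <- max(4, ceiling(sqrt(150)))
  breaks <- qnorm(seq(0, 1, length.out = k + 1), mean(v), sd(v))
  obs <- as.vector(table(cut(v, breaks)))
  chi2 <- sum((obs - 150 / k)^2 / (150 / k))
  expect_equal(chi2Normality(v), pchisq(chi2, k - 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the decision rule needs both significance and a warmer thrust ROI", {
  mk <- function(p, m1, m2) new("TestResult", tStat = 1, df = 30L,
                                pValue = p, mean1 = m1, mean2 = m2,
                                normalityP1 = NA_real_, normalityP2 = NA_real_,
                                warnings = character())
  expect_equal(decisionOutput(classify(mk(0.01, 0.7, 0.4), 0.05)), 1L)
  expect_equal(decisionOutput(classify(mk(0.20, 0.7, 0.4), 0.05)), 0L)
  # significant but colder thrust region: inadequate
  expect_equal(decisionOutput(classify(mk(0.01, 0.3, 0.6), 0.05)), 0L)
  # p equal to the threshold classifies as inadequate (strict comparison)
  expect_equal(decisionOutput(classify(mk(0.05, 0.7, 0.4), 0.05)), 0L)
})

test_that("output is non-decreasing in the threshold for a fixed test", {
  set.seed(13)
  for (i in 1:20) {
    t <- studentTTest(runif(16), runif(16), checkNormality = FALSE)
    outs <- vapply(seq(0.005, 0.5, length.out = 60),
                   function(th) decisionOutput(classify(t, th)), integer(1))
    expect_true(all(diff(outs) >= 0))
  }
})

test_that("end-to-end assessment composes deterministically", {
  # strong hot spot: adequate at the default threshold
  rec <- generatePhantom(phantomConfig(deltaTC = 1.0, noiseSdC = 0.05,
                                       seed = 21))
  res <- assessPair(rec$pair, rec$rois)
  expect_equal(decisionOutput(res), 1L)
  expect_lt(res@test@pValue, 0.001)

  res2 <- assessPair(rec$pair, rec$rois)
  expect_identical(res2@test@pValue, res@test@pValue)

  # identical grids in both ROIs: inadequate
  ph <- phantomThermal(phantomConfig(deltaTC = 0, noiseSdC = 0, biasC = 0,
                                     gradientCPerPx = 0, seed = 1))
  r0 <- assessRois(ph$frame, ph$roi1, ph$roi2)
  expect_equal(decisionOutput(r0), 0L)
  expect_equal(r0@test@pValue, 1)
})

test_that("assessment reports serialise the decision and its inputs", {
  rec <- generatePhantom(phantomConfig(deltaTC = 1.0, seed = 3))
  res <- assessPair(rec$pair, rec$rois)
  path <- withr::local_tempfile(fileext = ".json")
  writeAssessment(res, rec$rois, path = path)
  rep <- jsonlite::fromJSON(path)
  expect_equal(rep$output, decisionOutput(res))
  expect_equal(rep$p_value, res@test@pValue)
  expect_equal(rep$rois$axis_x, rec$rois@axisX)
})
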