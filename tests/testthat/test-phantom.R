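test_that("phantoms are bit-reproducible and validated", {
  cfg <- phantomConfig(deltaTC = 0.8, seed = 33)
  a <- phantomThermal(cfg)
  b <- phantomThermal(cfg)
  expect_identical(temps(a$frame), temps(b$frame))

  recA <- generatePhantom(cfg)
  recB <- generatePhantom(cfg)
  expect_identical(temps(recA$pair@thermal), temps(recB$pair@thermal))
  expect_identical(recA$rois@roi1@x0, recB$rois@roi1@x0)

  # hot-spot box must stay inside the thermal frame
  expect_error(phantomConfig(hotspotCenter = c(5, 60)), "config error")
  expect_error(phantomConfig(deltaTC = -1), "config error")
})

test_that("a noiseless null phantom yields identical ROIs and p = 1", {
  ph <- phantomThermal(phantomConfig(deltaTC = 0, noiseSdC = 0, biasC = 0,
                                     seed = 4))
  a <- extractRoi(ph$frame, ph$roi1)
  b <- extractRoi(ph$frame, ph$roi2)
  expect_identical(a, b)                 # gradient is vertical, rows shared
  pv <- partitionPair(a, b)
  expect_equal(partMeans(pv[[1]]), partMeans(pv[[2]]))
  r <- studentTTest(pv[[1]], pv[[2]], checkNormality = FALSE)
  expect_equal(c(r@tStat, r@pValue), c(0, 1))
})

test_that("the noiseless ROI mean difference matches the separable bump sum", {
  cfg <- phantomConfig(deltaTC = 1.3, noiseSdC = 0, quantizationC = 0,
                       biasC = 0, seed = 2)
  ph <- phantomThermal(cfg)
  boxMean <- function(roi) {
    xs <- roi@x0:(roi@x0 + roi@w - 1L)
    ys <- roi@y0:(roi@y0 + roi@h - 1L)
    sum(exp(-(xs - cfg$hotspotCenter[1])^2 / (2 * cfg$hotspotSigmaPx^2))) *
      sum(exp(-(ys - cfg$hotspotCenter[2])^2 / (2 * cfg$hotspotSigmaPx^2))) /
      (roi@w * roi@h)
  }
  measured <- mean(extractRoi(ph$frame, ph$roi1)) -
    mean(extractRoi(ph$frame, ph$roi2))
  expected <- cfg$deltaTC * (boxMean(ph$roi1) - boxMean(ph$roi2))
  expect_lt(abs(measured - expected), 1e-6)
})

test_that("a per-image bias never changes the p-value", {
  # +/- 3 degC is a multiple of the 0.1 degC quantisation step, so the whole
  # grid shifts by an exact number of steps and joint normalisation cancels it
  for (seed in c(1, 2, 3)) {
    ps <- vapply(c(0, 3, -3), function(bias) {
      ph <- phantomThermal(phantomConfig(deltaTC = 0.5, biasC = bias,
                                         seed = seed))
      assessRois(ph$frame, ph$roi1, ph$roi2)@test@pValue
    }, numeric(1))
    # equality to machine precision: the shift crosses the quantiser, whose
    # floating-point boundaries can move by an ulp
    expect_equal(ps[2], ps[1], tolerance = 1e-12)
    expect_equal(ps[3], ps[1], tolerance = 1e-12)
  }
})

test_that("studies carry the requested class structure deterministically", {
  recs <- generateStudy(26, 10, 1.0, seed = 50)
  expect_length(recs, 36)
  labels <- vapply(recs, `[[`, integer(1), "label")
  expect_equal(sum(labels == 1), 26)
  expect_equal(sum(labels == 0), 10)
  expect_equal(vapply(recs, `[[`, numeric(1), "trueDeltaTC"),
               rep(c(1, 0), c(26, 10)))

  nulls <- generateStudy(0, 5, seed = 1)
  expect_length(nulls, 5)
  expect_true(all(vapply(nulls, `[[`, integer(1), "label") == 0L))

  again <- generateStudy(26, 10, 1.0, seed = 50)
  expect_identical(temps(again[[7]]$pair@thermal),
                   temps(recs[[7]]$pair@thermal))

  # a no-signal adequate class keeps its labels (chance-level control)
  ctrl <- generateStudy(4, 2, 0, seed = 9)
  expect_equal(vapply(ctrl, `[[`, integer(1), "label"),
               rep(c(1L, 0L), c(4, 2)))
})

test_that("strong-effect records score significant with the right direction", {
  recs <- generateStudy(8, 0, 1.0, seed = 60, noiseSdC = 0.05)
  sc <- studyToScores(recs)
  expect_true(all(sc$p_value < 0.001))
  expect_true(all(sc$direction_ok))
  expect_true(all(sc$label == 1L))
  expect_equal(nrow(studyToScores(list())), 0L)
})

test_that("null p-values are approximately uniform under the iid null", {
  # flat baseline: the sampling distribution the t-test assumes
  ps <- vapply(1:500, function(s) {
    ph <- phantomThermal(phantomConfig(deltaTC = 0, gradientCPerPx = 0,
                                       seed = s))
    a <- extractRoi(ph$frame, ph$roi1)
    b <- extractRoi(ph$frame, ph$roi2)
    pv <- partitionPair(a, b)
    studentTTest(pv[[1]], pv[[2]], checkNormality = FALSE)@pValue
  }, numeric(1))
  d <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(d, 0.1)
})

test_that("written studies round-trip through the file interfaces", {
  dir <- withr::local_tempdir()
  recs <- generateStudy(2, 1, 1.0, seed = 70, rgbSize = c(160L, 120L))
  writeStudy(recs, dir)
  expect_true(all(file.exists(file.path(dir,
    c("thermal_001.csv", "rgb_001.png", "roi_001.json", "manifest.csv")))))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(man$label, c(1, 1, 0))

  tf <- readThermal(file.path(dir, "thermal_002.csv"))
  expect_lt(max(abs(temps(tf) - temps(recs[[2]]$pair@thermal))), 1e-6)
  rois <- readRoiConfig(file.path(dir, "roi_003.json"))
  expect_equal(rois[[1]]@roi1@x0, recs[[3]]$rois@roi1@x0)
})
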