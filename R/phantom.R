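## Synthetic thermal phantom: paired RGB/thermal back images with the
## statistical structure the method assumes — a smooth baseline skin
## temperature field, a localised pressure-induced warm region, and the
## sensor-error model of a low-cost 160 x 120 smartphone-attached thermal
## camera (Gaussian noise at the 100 mK sensitivity, a per-image uniform
## bias within the +/- 3 degC accuracy, and quantisation).

#' Phantom configuration
#'
#' Defaults emulate the study conditions: a 1440 x 1080 visual image paired
#' with a 160 x 120 thermal grid, a baseline skin temperature of 33 degC
#' with a mild vertical gradient, an isotropic Gaussian hot spot where the
#' brace pressed (its peak elevation `deltaTC` stands in for the
#' thermoelastic temperature rise; 0 models inadequate pressure), sensor
#' noise with sd 0.1 degC (the camera's 100 mK thermal sensitivity),
#' quantisation to 0.1 degC steps, and a per-image calibration bias drawn
#' uniformly within the camera's +/- 3 degC accuracy.
#'
#' @param rgbSize,thermalSize integer `c(width, height)` of the two frames.
#' @param baselineC baseline skin temperature, degC.
#' @param gradientCPerPx vertical linear trend, degC per pixel row.
#' @param hotspotCenter `c(x, y)` of the hot spot in thermal pixels.
#' @param hotspotSigmaPx Gaussian spatial spread, thermal pixels.
#' @param deltaTC peak temperature elevation of the hot spot, degC (>= 0).
#' @param noiseSdC additive Gaussian sensor noise sd, degC.
#' @param quantizationC digitisation step, degC.
#' @param biasC fixed per-image offset in degC, or `NULL` to draw it
#'   uniformly from `[-biasRangeC, biasRangeC]`.
#' @param biasRangeC half-width of the bias distribution, degC.
#' @param adequacyCutoffC label cutoff: label is 1 iff `deltaTC >= cutoff`.
#' @param seed integer seed; the phantom is bit-reproducible given it.
#' @return a validated configuration list of class `PhantomConfig`.
#' @export
phantomConfig <- function(rgbSize = c(1440L, 1080L),
                          thermalSize = c(160L, 120L),
                          baselineC = 33.0, gradientCPerPx = 0.002,
                          hotspotCenter = c(40L, 60L), hotspotSigmaPx = 6,
                          deltaTC = 1.0, noiseSdC = 0.1,
                          quantizationC = 0.1, biasC = NULL,
                          biasRangeC = 3.0, adequacyCutoffC = 0.5,
                          seed = 42L) {
  cfg <- list(rgbSize = as.integer(rgbSize),
              thermalSize = as.integer(thermalSize),
              baselineC = baselineC, gradientCPerPx = gradientCPerPx,
              hotspotCenter = hotspotCenter,
              hotspotSigmaPx = hotspotSigmaPx, deltaTC = deltaTC,
              noiseSdC = noiseSdC, quantizationC = quantizationC,
              biasC = biasC, biasRangeC = biasRangeC,
              adequacyCutoffC = adequacyCutoffC, seed = as.integer(seed))
  if (any(cfg$rgbSize < 1L) || any(cfg$thermalSize < 1L))
    stop("config error: frame sizes must be positive")
  if (cfg$deltaTC < 0 || cfg$noiseSdC < 0)
    stop("config error: deltaTC and noiseSdC must be non-negative")
  box <- .hotspotBox(cfg)
  tw <- cfg$thermalSize[1]
  if (box$x0 < 0 || box$y0 < 0 ||
      box$x0 + box$w > tw || box$y0 + box$h > cfg$thermalSize[2])
    stop("config error: hot-spot box [", box$x0, ",", box$x0 + box$w,
         ") x [", box$y0, ",", box$y0 + box$h, ") exits the thermal frame")
  if (2L * (tw %/% 2L) - box$x0 - box$w < 0 ||
      2L * (tw %/% 2L) - box$x0 > tw)
    stop("config error: mirror of the hot-spot box exits the thermal frame")
  class(cfg) <- "PhantomConfig"
  cfg
}

# flat skin-toned visual companion
.flatSkinRgb <- function(w, h) {
  skin <- c(224, 172, 105)
  rgbFrame(array(rep(skin, each = h * w), dim = c(h, w, 3L)))
}

# the +/- 2 sigma box around the hot spot, in thermal pixels
.hotspotBox <- function(cfg) {
  s2 <- ceiling(2 * cfg$hotspotSigmaPx)
  list(x0 = cfg$hotspotCenter[1] - s2, y0 = cfg$hotspotCenter[2] - s2,
       w = 2L * s2, h = 2L * s2)
}

#' Simulate the thermal grid and its ROI pair
#'
#' The core of the phantom: the thermal temperature field
#' `baseline + gradient * y + deltaTC * exp(-d^2 / (2 sigma^2)) + bias +
#' noise`, quantised to `quantizationC` steps, together with the thrust ROI
#' (the +/- 2 sigma box around the hot spot) and its mirror about the
#' frame's vertical midline, both in thermal coordinates. Deterministic
#' given `cfg$seed`. [generatePhantom()] wraps this with the RGB companion.
#'
#' @param cfg a [phantomConfig()].
#' @return list with `frame` ([ThermalFrame-class]), `roi1`, `roi2`
#'   (thermal-frame [Rect-class]), `biasC` (the bias actually applied).
#' @export
phantomThermal <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  w <- cfg$thermalSize[1]; h <- cfg$thermalSize[2]
  set.seed(cfg$seed)
  bias <- if (is.null(cfg$biasC))
    stats::runif(1, -cfg$biasRangeC, cfg$biasRangeC) else cfg$biasC
  x <- 0:(w - 1L); y <- 0:(h - 1L)
  bump <- exp(-outer((y - cfg$hotspotCenter[2])^2,
                     (x - cfg$hotspotCenter[1])^2, "+") /
                (2 * cfg$hotspotSigmaPx^2))
  t <- cfg$baselineC + cfg$gradientCPerPx * y +   # gradient recycles down rows
    cfg$deltaTC * bump + bias
  if (cfg$noiseSdC > 0)
    t <- t + matrix(stats::rnorm(h * w, sd = cfg$noiseSdC), h, w)
  if (cfg$quantizationC > 0)
    t <- round(t / cfg$quantizationC) * cfg$quantizationC
  box <- .hotspotBox(cfg)
  roi1 <- rect2d(box$x0, box$y0, box$w, box$h, frame = "thermal")
  roi2 <- mirrorRoi(roi1, w %/% 2L, frameWidth = w)
  list(frame = thermalFrame(t, quantizationC = cfg$quantizationC),
       roi1 = roi1, roi2 = roi2, biasC = bias)
}

#' Generate one synthetic phantom record
#'
#' Produces a full record: the thermal frame from [phantomThermal()], a flat
#' skin-toned RGB companion at `rgbSize`, the registered [ImagePair-class],
#' the thrust/mirror [RoiPair-class] expressed in RGB coordinates (as an
#' operator would supply them), the 0/1 adequacy label and the true hot-spot
#' amplitude.
#'
#' @param cfg a [phantomConfig()].
#' @param rgb optional prebuilt [RgbFrame-class] of size `rgbSize` to reuse
#'   across the records of a study (the companion is flat, so sharing it is
#'   faithful and avoids rebuilding a multi-megapixel array per record).
#' @return list of class `PhantomRecord` with elements `pair`, `rois`,
#'   `label`, `trueDeltaTC`, `thermal` (the [phantomThermal()] output).
#' @export
generatePhantom <- function(cfg, rgb = NULL) {
  th <- phantomThermal(cfg)
  rw <- cfg$rgbSize[1]; rh <- cfg$rgbSize[2]
  if (is.null(rgb)) rgb <- .flatSkinRgb(rw, rh)
  stopifnot(all(frameDim(rgb) == c(rh, rw)))
  pair <- makePair(rgb, th$frame)
  sx <- pair@scaleX; sy <- pair@scaleY
  roi1rgb <- rect2d(round(th$roi1@x0 / sx), round(th$roi1@y0 / sy),
                    round(th$roi1@w / sx), round(th$roi1@h / sy),
                    frame = "rgb")
  axisRgb <- round((cfg$thermalSize[1] %/% 2L) / sx)
  rois <- roiPair(roi1rgb, axisRgb, frameWidth = rw)
  rec <- list(pair = pair, rois = rois,
              label = as.integer(cfg$deltaTC >= cfg$adequacyCutoffC),
              trueDeltaTC = cfg$deltaTC, thermal = th)
  class(rec) <- "PhantomRecord"
  rec
}

#' Generate a labelled phantom study
#'
#' A dataset with the study's class structure: `nAdequate` records with a
#' hot spot of amplitude `deltaTAdequateC` (label 1) followed by
#' `nInadequate` records with no hot spot (label 0). Record i uses seed
#' `seed + i`, so the whole study is reproducible while every image differs.
#' Labels follow class membership: the per-record adequacy cutoff is set to
#' `deltaTAdequateC` for the adequate class and above zero for the
#' inadequate class, so an adequate class generated with
#' `deltaTAdequateC = 0` (a no-signal control) still carries label 1.
#'
#' @param nAdequate,nInadequate class counts (study defaults 26 and 10).
#' @param deltaTAdequateC hot-spot amplitude for the adequate class, degC.
#' @param seed base integer seed.
#' @param ... further arguments passed to [phantomConfig()] (e.g.
#'   `noiseSdC`, `thermalSize`).
#' @return list of `PhantomRecord` objects.
#' @export
generateStudy <- function(nAdequate = 26, nInadequate = 10,
                          deltaTAdequateC = 1.0, seed = 42, ...) {
  deltas <- c(rep(deltaTAdequateC, nAdequate), rep(0, nInadequate))
  cutoffs <- c(rep(deltaTAdequateC, nAdequate),
               rep(max(deltaTAdequateC, 0.5), nInadequate))
  rgb <- NULL
  lapply(seq_along(deltas), function(i) {
    cfg <- phantomConfig(deltaTC = deltas[i], seed = seed + i,
                         adequacyCutoffC = cutoffs[i], ...)
    if (is.null(rgb)) rgb <<- .flatSkinRgb(cfg$rgbSize[1], cfg$rgbSize[2])
    generatePhantom(cfg, rgb = rgb)
  })
}

#' Score the records of a phantom study
#'
#' Runs the assessment pipeline — mapping, extraction, joint grayscale,
#' partitioning, t-test — on every record *without* thresholding, emitting
#' the score dataset the evaluation consumes: p-value, direction flag
#' (thrust region warmer than reference) and label.
#'
#' @param records list of `PhantomRecord` objects from [generateStudy()].
#' @param nRows,nCols partition counts (default 4 x 4).
#' @return score data.frame as from [scoreRecords()].
#' @export
studyToScores <- function(records, nRows = 4, nCols = 4) {
  if (!length(records))
    return(scoreRecords(numeric(0), logical(0), integer(0)))
  rows <- lapply(records, function(rec) {
    m <- .mapPairToThermal(rec$rois, rec$pair)
    a <- extractRoi(rec$pair@thermal, m$roi1)
    b <- extractRoi(rec$pair@thermal, m$roi2)
    pv <- partitionPair(a, b, nRows, nCols)
    t <- studentTTest(pv[[1]], pv[[2]], checkNormality = FALSE)
    c(t@pValue, t@mean1 > t@mean2, rec$label)
  })
  m <- do.call(rbind, rows)
  scoreRecords(m[, 1], as.logical(m[, 2]), m[, 3])
}

#' Write a phantom study to a directory
#'
#' One `thermal_XXX.csv`, `rgb_XXX.png` and `roi_XXX.json` per record plus a
#' `manifest.csv` with labels and true hot-spot amplitudes.
#'
#' @param records list of `PhantomRecord` objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    tag <- sprintf("%03d", i)
    writeThermal(rec$pair@thermal, file.path(dir, paste0("thermal_", tag,
                                                         ".csv")))
    writeRgb(rec$pair@rgb, file.path(dir, paste0("rgb_", tag, ".png")))
    r1 <- rec$rois@roi1
    jsonlite::write_json(list(
      roi1 = list(x0 = r1@x0, y0 = r1@y0, w = r1@w, h = r1@h),
      axis_x = rec$rois@axisX, frame = r1@frame),
      file.path(dir, paste0("roi_", tag, ".json")), auto_unbox = TRUE)
    data.frame(record = tag, label = rec$label,
               true_delta_t_c = rec$trueDeltaTC)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
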