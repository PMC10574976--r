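#' Construct a ThermalFrame
#'
#' @param temperatures numeric matrix of calibrated temperatures in degrees C.
#' @param emissivity surface emissivity in (0, 1]; human skin is about 0.97.
#' @param ambientC ambient temperature in degrees C, or `NA`.
#' @param distanceM camera-to-subject distance in metres, or `NA`.
#' @param quantizationC camera digitisation step in degrees C, or `NA`.
#' @return a [ThermalFrame-class].
#' @examples
#' tf <- thermalFrame(matrix(c(30, 32, 31, 33), 2))
#' frameDim(tf)
#' @export
thermalFrame <- function(temperatures, emissivity = 0.97, ambientC = NA_real_,
                         distanceM = NA_real_, quantizationC = NA_real_) {
  if (!is.matrix(temperatures)) temperatures <- as.matrix(temperatures)
  storage.mode(temperatures) <- "double"
  new("ThermalFrame", temperatures = temperatures,
      meta = list(emissivity = emissivity, ambient_c = ambientC,
                  distance_m = distanceM, quantization_c = quantizationC))
}

#' Construct an RgbFrame
#'
#' @param channels a height x width x 3 array of intensities in [0, 255], or a
#'   height x width matrix (replicated across the three channels, as for
#'   grayscale sources).
#' @return an [RgbFrame-class].
#' @export
rgbFrame <- function(channels) {
  if (is.matrix(channels))
    channels <- array(rep(channels, 3L), dim = c(dim(channels), 3L))
  storage.mode(channels) <- "double"
  new("RgbFrame", channels = channels)
}

#' Construct a Rect
#'
#' Half-open pixel rectangle `[x0, x0 + w) x [y0, y0 + h)` in 0-based
#' coordinates, origin top-left, x = column, y = row.
#'
#' @param x0,y0 non-negative integer top-left corner.
#' @param w,h positive integer width and height.
#' @param frame `"rgb"` or `"thermal"`.
#' @return a [Rect-class].
#' @examples
#' rect2d(50, 20, 10, 30)
#' @export
rect2d <- function(x0, y0, w, h, frame = "rgb") {
  new("Rect", x0 = as.integer(x0), y0 = as.integer(y0),
      w = as.integer(w), h = as.integer(h), frame = frame)
}

#' Construct a RoiPair from ROI #1 and the backbone axis
#'
#' Builds the mirror reference ROI #2 by reflecting ROI #1 about the vertical
#' backbone column and couples the two.
#'
#' @param roi1 [Rect-class], the thrust region.
#' @param axisX integer backbone axis column (same frame as `roi1`).
#' @param frameWidth optional frame width used to check that the reflection
#'   stays inside the image.
#' @return a [RoiPair-class].
#' @seealso [mirrorRoi()]
#' @export
roiPair <- function(roi1, axisX, frameWidth = NULL) {
  roi2 <- mirrorRoi(roi1, axisX, frameWidth = frameWidth)
  new("RoiPair", roi1 = roi1, roi2 = roi2, axisX = as.integer(axisX))
}

## ---- accessors ----

#' Dimensions and content accessors
#'
#' `temps()` returns the temperature matrix of a [ThermalFrame-class];
#' `frameDim()` returns `c(height, width)` for thermal or RGB frames;
#' `frameMeta()` the metadata list; `partMeans()` the numeric vector inside a
#' [PartitionVector-class]; `decisionOutput()` the 0/1 decision of an
#' [AssessmentResult-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
temps <- function(x) x@temperatures

#' @rdname accessors
#' @export
frameDim <- function(x) {
  if (is(x, "ThermalFrame")) dim(x@temperatures)
  else if (is(x, "RgbFrame")) dim(x@channels)[1:2]
  else stop("no frame dimensions for class ", class(x))
}

#' @rdname accessors
#' @export
frameMeta <- function(x) x@meta

#' @rdname accessors
#' @export
partMeans <- function(x) x@means

#' @rdname accessors
#' @export
decisionOutput <- function(x) x@output

#' @rdname accessors
#' @export
testResult <- function(x) x@test

## ---- show methods ----

setMethod("show", "ThermalFrame", function(object) {
  d <- dim(object@temperatures)
  cat(sprintf("ThermalFrame: %d x %d px, %.2f-%.2f degC, emissivity %.2f\n",
              d[2], d[1], min(object@temperatures), max(object@temperatures),
              object@meta$emissivity))
})

setMethod("show", "RgbFrame", function(object) {
  d <- dim(object@channels)
  cat(sprintf("RgbFrame: %d x %d px, 3 channels\n", d[2], d[1]))
})

setMethod("show", "ImagePair", function(object) {
  cat(sprintf("ImagePair: rgb %d x %d / thermal %d x %d (scale %.4f, %.4f)\n",
              frameDim(object@rgb)[2], frameDim(object@rgb)[1],
              frameDim(object@thermal)[2], frameDim(object@thermal)[1],
              object@scaleX, object@scaleY))
})

setMethod("show", "Rect", function(object) {
  cat(sprintf("Rect[%s]: x0=%d y0=%d w=%d h=%d\n", object@frame,
              object@x0, object@y0, object@w, object@h))
})

setMethod("show", "RoiPair", function(object) {
  cat(sprintf("RoiPair (axis x=%d):\n  ROI #1 ", object@axisX))
  show(object@roi1)
  cat("  ROI #2 ")
  show(object@roi2)
})

setMethod("show", "PartitionVector", function(object) {
  cat(sprintf("PartitionVector: %d x %d = %d subregion means in [%.3f, %.3f]\n",
              object@nRows, object@nCols, length(object@means),
              min(object@means), max(object@means)))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: t = %.4f, df = %d, p = %.4g; means %.4f vs %.4f\n",
              object@tStat, object@df, object@pValue,
              object@mean1, object@mean2))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "AssessmentResult", function(object) {
  cat(sprintf("AssessmentResult: output = %d (%s) at threshold %.3f\n",
              object@output,
              if (object@output == 1L) "adequate" else "inadequate",
              object@threshold))
  show(object@test)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d subsets, mean accuracy (%.1f +/- %.1f)%% (k = %g)\n",
              nrow(object@perSubset), object@meanAccuracyPct,
              object@expandedUPct, object@coverageK))
  print(object@perSubset, row.names = FALSE)
})
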