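#' @import methods
NULL

#' ThermalFrame: a calibrated temperature grid
#'
#' A 2D grid of calibrated skin temperatures in degrees Celsius together with
#' acquisition metadata. This is the quantity every downstream statistic is
#' computed from; pixel intensities of the visual (RGB) companion image are
#' never used quantitatively.
#'
#' Coordinates are 0-based with x = column, y = row and the origin at the
#' top-left pixel. The temperature matrix is stored row-major in the sense
#' that `temperatures[y + 1, x + 1]` is the pixel at (x, y).
#'
#' @slot temperatures numeric matrix of temperatures (degrees C), rows = image
#'   rows, columns = image columns.
#' @slot meta named list with elements `emissivity` (dimensionless, in (0, 1],
#'   human skin is about 0.97), `ambient_c`, `distance_m` and
#'   `quantization_c` (the camera's digitisation step in degrees C; `NA` when
#'   unknown).
#'
#' @seealso [thermalFrame()], [readThermal()], [writeThermal()]
#' @export
setClass("ThermalFrame",
  representation(temperatures = "matrix", meta = "list"),
  validity = function(object) {
    msg <- character()
    t <- object@temperatures
    if (!is.numeric(t) || length(t) == 0L)
      msg <- c(msg, "temperatures must be a non-empty numeric matrix")
    else if (!all(is.finite(t)))
      msg <- c(msg, "all temperatures must be finite")
    e <- object@meta$emissivity
    if (!is.null(e) && !is.na(e) && (e <= 0 || e > 1))
      msg <- c(msg, "emissivity must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' RgbFrame: a three-channel visual image
#'
#' The high-resolution visual companion of a thermal acquisition. The operator
#' selects regions of interest on this image (never on the thermal one, to
#' avoid confirmation bias); its pixel values otherwise play no role in the
#' decision.
#'
#' @slot channels numeric array of dimension height x width x 3 with
#'   intensities in [0, 255].
#'
#' @seealso [rgbFrame()], [readRgb()]
#' @export
setClass("RgbFrame",
  representation(channels = "array"),
  validity = function(object) {
    d <- dim(object@channels)
    if (length(d) != 3L || d[3] != 3L)
      return("channels must be a height x width x 3 array")
    if (d[1] < 1L || d[2] < 1L)
      return("image dimensions must be positive")
    v <- object@channels
    if (!all(is.finite(v)) || any(v < 0) || any(v > 255))
      return("intensities must be finite and in [0, 255]")
    TRUE
  }
)

#' ImagePair: co-registered RGB and thermal frames
#'
#' Couples a visual frame with its thermal frame and records the anisotropic
#' scale factors (thermal size / RGB size) used to map operator-selected
#' rectangles from RGB coordinates onto the thermal grid. Registration is
#' pure scaling: both streams come from one rigidly attached device, so no
#' translation or rotation is modelled.
#'
#' @slot rgb an [RgbFrame-class].
#' @slot thermal a [ThermalFrame-class].
#' @slot scaleX,scaleY numeric scale factors in (0, 1],
#'   `thermal width / rgb width` and `thermal height / rgb height`.
#'
#' @seealso [makePair()], [mapToThermal()]
#' @export
setClass("ImagePair",
  representation(rgb = "RgbFrame", thermal = "ThermalFrame",
                 scaleX = "numeric", scaleY = "numeric"),
  validity = function(object) {
    if (object@scaleX <= 0 || object@scaleX > 1 ||
        object@scaleY <= 0 || object@scaleY > 1)
      return("scale factors must lie in (0, 1]")
    TRUE
  }
)

#' Rect: a half-open pixel rectangle
#'
#' An axis-aligned rectangle in pixel coordinates, half-open on both axes:
#' it covers columns `[x0, x0 + w)` and rows `[y0, y0 + h)`. Coordinates are
#' 0-based with the origin at the top-left. The `frame` tag records whether
#' the coordinates refer to the RGB or the thermal grid; geometric operations
#' refuse to mix frames.
#'
#' @slot x0,y0 integer top-left corner (0-based, non-negative).
#' @slot w,h integer width and height (positive).
#' @slot frame `"rgb"` or `"thermal"`.
#'
#' @seealso [rect2d()], [mirrorRoi()], [mapToThermal()], [extractRoi()]
#' @export
setClass("Rect",
  representation(x0 = "integer", y0 = "integer",
                 w = "integer", h = "integer", frame = "character"),
  validity = function(object) {
    msg <- character()
    if (object@x0 < 0L || object@y0 < 0L)
      msg <- c(msg, "x0 and y0 must be non-negative")
    if (object@w < 1L || object@h < 1L)
      msg <- c(msg, "w and h must be positive")
    if (!object@frame %in% c("rgb", "thermal"))
      msg <- c(msg, "frame must be 'rgb' or 'thermal'")
    if (length(msg)) msg else TRUE
  }
)

#' RoiPair: thrust region, mirror reference and backbone axis
#'
#' The two regions the decision compares: ROI #1 is the rectangle where the
#' brace is prescribed to push; ROI #2 is its reflection across the vertical
#' backbone axis and serves as the within-patient reference. Both share width
#' and height by construction.
#'
#' @slot roi1 [Rect-class], the pressure (thrust) region.
#' @slot roi2 [Rect-class], the mirror reference region.
#' @slot axisX integer column of the backbone axis in the same frame.
#'
#' @seealso [roiPair()], [readRoiConfig()], [assessPair()]
#' @export
setClass("RoiPair",
  representation(roi1 = "Rect", roi2 = "Rect", axisX = "integer"),
  validity = function(object) {
    r1 <- object@roi1; r2 <- object@roi2
    msg <- character()
    if (r1@w != r2@w || r1@h != r2@h)
      msg <- c(msg, "roi1 and roi2 must have identical width and height")
    if (r1@frame != r2@frame)
      msg <- c(msg, "roi1 and roi2 must live in the same frame")
    if (2L * object@axisX - r1@x0 - r1@w != r2@x0)
      msg <- c(msg, "roi2 must be the reflection of roi1 about x = axisX")
    if (length(msg)) msg else TRUE
  }
)

#' GrayRoi: a jointly min-max normalised ROI
#'
#' A temperature sub-grid mapped affinely to [0, 1], white (1) at the joint
#' maximum temperature and black (0) at the joint minimum of the ROI *pair*.
#' Normalisation over the pair, not per ROI, is what keeps the between-ROI
#' temperature ordering meaningful after conversion.
#'
#' @slot values numeric matrix in [0, 1].
#' @slot sourceMinC,sourceMaxC the joint temperature bounds (degrees C) used
#'   for normalisation.
#'
#' @seealso [toGrayscaleJoint()]
#' @export
setClass("GrayRoi",
  representation(values = "matrix", sourceMinC = "numeric",
                 sourceMaxC = "numeric"),
  validity = function(object) {
    v <- object@values
    if (!all(is.finite(v)) || any(v < 0) || any(v > 1))
      return("gray values must be finite and in [0, 1]")
    if (object@sourceMinC > object@sourceMaxC)
      return("sourceMinC must not exceed sourceMaxC")
    TRUE
  }
)

#' PartitionVector: per-subregion mean intensities of one ROI
#'
#' The length-L = N x M vector of arithmetic means of the N x M subregions of
#' a grayscale ROI, in row-major order (subregion (i, j) precedes (i, j+1)).
#' One such vector per ROI is what the two-sample t-test compares.
#'
#' @slot means numeric vector of length `nRows * nCols`.
#' @slot nRows,nCols integer partition counts (N horizontal slices, M
#'   vertical slices).
#'
#' @seealso [partitionMeans()], [studentTTest()]
#' @export
setClass("PartitionVector",
  representation(means = "numeric", nRows = "integer", nCols = "integer"),
  validity = function(object) {
    if (object@nRows < 1L || object@nCols < 1L)
      return("nRows and nCols must be positive")
    if (length(object@means) != object@nRows * object@nCols)
      return("length(means) must equal nRows * nCols")
    if (!all(is.finite(object@means)))
      return("means must be finite")
    TRUE
  }
)

#' TestResult: outcome of the two-sample comparison
#'
#' Holds the pooled-variance Student's t statistic between the two partition
#' vectors, its two-sided p-value on 2L - 2 degrees of freedom, the two group
#' means, and (advisory) chi-square normality p-values for each vector.
#'
#' @slot tStat numeric t statistic.
#' @slot df integer degrees of freedom (2L - 2).
#' @slot pValue numeric two-sided p-value in [0, 1].
#' @slot mean1,mean2 numeric group means (ROI #1 and ROI #2).
#' @slot normalityP1,normalityP2 numeric chi-square goodness-of-fit p-values,
#'   `NA` when not computed.
#' @slot warnings character vector of advisory messages (degenerate variance,
#'   normality rejection).
#'
#' @seealso [studentTTest()], [classify()]
#' @export
setClass("TestResult",
  representation(tStat = "numeric", df = "integer", pValue = "numeric",
                 mean1 = "numeric", mean2 = "numeric",
                 normalityP1 = "numeric", normalityP2 = "numeric",
                 warnings = "character"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      return("pValue must lie in [0, 1]")
    if (object@df < 1L)
      return("df must be positive")
    TRUE
  }
)

#' AssessmentResult: the binary adequacy decision
#'
#' The end product of the pipeline for one ROI pair: `output` is 1 (adequate
#' pressure) exactly when the t-test p-value is strictly below the threshold
#' *and* the thrust region is on average warmer than its mirror reference;
#' otherwise 0 (inadequate).
#'
#' @slot test a [TestResult-class].
#' @slot threshold numeric decision threshold in (0, 1).
#' @slot output integer, 0 or 1.
#'
#' @seealso [classify()], [assessPair()]
#' @export
setClass("AssessmentResult",
  representation(test = "TestResult", threshold = "numeric",
                 output = "integer"),
  validity = function(object) {
    if (object@threshold <= 0 || object@threshold >= 1)
      return("threshold must lie in (0, 1)")
    if (!object@output %in% c(0L, 1L))
      return("output must be 0 or 1")
    want <- as.integer(object@test@pValue < object@threshold &&
                         object@test@mean1 > object@test@mean2)
    if (object@output != want)
      return("output inconsistent with (pValue < threshold and mean1 > mean2)")
    TRUE
  }
)

#' EvalReport: balanced-subset LOOCV performance summary
#'
#' Per-subset leave-one-out accuracies with their type-A standard
#' uncertainties, the overall mean accuracy, the first-order propagated
#' uncertainty of that mean, and the expanded uncertainty obtained with the
#' coverage factor. All values are carried at full precision; rounding to one
#' decimal is presentation only.
#'
#' @slot perSubset data.frame with columns `subset`, `accuracy_pct`, `u_pct`.
#' @slot foldOutcomes list of binary vectors, one per subset (1 = fold
#'   classified correctly).
#' @slot meanAccuracyPct numeric mean of the subset accuracies (percent).
#' @slot uMeanPct numeric propagated standard uncertainty of the mean
#'   (percent).
#' @slot coverageK numeric coverage factor (2 for ~95 percent confidence).
#' @slot expandedUPct numeric expanded uncertainty `coverageK * uMeanPct`.
#'
#' @seealso [evaluateSystem()]
#' @export
setClass("EvalReport",
  representation(perSubset = "data.frame", foldOutcomes = "list",
                 meanAccuracyPct = "numeric", uMeanPct = "numeric",
                 coverageK = "numeric", expandedUPct = "numeric"),
  validity = function(object) {
    need <- c("subset", "accuracy_pct", "u_pct")
    if (!all(need %in% names(object@perSubset)))
      return("perSubset must have columns subset, accuracy_pct, u_pct")
    if (abs(object@meanAccuracyPct - mean(object@perSubset$accuracy_pct)) > 1e-9)
      return("meanAccuracyPct must equal the mean of the subset accuracies")
    if (abs(object@expandedUPct - object@coverageK * object@uMeanPct) > 1e-9)
      return("expandedUPct must equal coverageK * uMeanPct")
    TRUE
  }
)
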