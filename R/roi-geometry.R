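## ROI geometry: mirror construction about the backbone axis, RGB-to-thermal
## mapping, sub-grid extraction, ROI config I/O.

# round half up, platform-independent (base round() rounds half to even)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Reflect ROI #1 about the backbone axis
#'
#' Constructs the mirror reference rectangle: the reflection of `roi1` about
#' the vertical line `x = axisX`, i.e. `x0' = 2 * axisX - x0 - w` with y, w, h
#' unchanged (the `- w` term accounts for the half-open convention). A
#' rectangle centred on the axis maps onto itself.
#'
#' @param roi1 [Rect-class] to reflect.
#' @param axisX integer backbone axis column.
#' @param frameWidth optional frame width; when given, a reflection extending
#'   past it is rejected.
#' @return the reflected [Rect-class].
#' @examples
#' mirrorRoi(rect2d(50, 20, 10, 30), 80)   # x0 = 100
#' @export
mirrorRoi <- function(roi1, axisX, frameWidth = NULL) {
  x0p <- 2L * as.integer(axisX) - roi1@x0 - roi1@w
  if (x0p < 0L)
    stop("geometry error: mirrored ROI starts at x = ", x0p,
         " (", -x0p, " px left of the frame)")
  if (!is.null(frameWidth) && x0p + roi1@w > frameWidth)
    stop("geometry error: mirrored ROI ends at x = ", x0p + roi1@w,
         " (", x0p + roi1@w - frameWidth, " px past the frame width ",
         frameWidth, ")")
  rect2d(x0p, roi1@y0, roi1@w, roi1@h, frame = roi1@frame)
}

#' Map an RGB-frame rectangle onto the thermal grid
#'
#' Scales an operator-selected rectangle from RGB pixel coordinates to the
#' thermal grid of an [ImagePair-class]: origin by floor, extent by round
#' half up, with degenerate extents promoted to one pixel and the result
#' clipped to the thermal bounds. Floor/round-half-up make the mapping
#' deterministic across platforms.
#'
#' @param roi [Rect-class] with `frame == "rgb"`.
#' @param pair the [ImagePair-class] providing the scale factors.
#' @return a [Rect-class] with `frame == "thermal"`, never empty.
#' @examples
#' rgb <- rgbFrame(matrix(128, 1080, 1440))
#' th <- thermalFrame(matrix(33, 120, 160))
#' mapToThermal(rect2d(450, 540, 90, 90), makePair(rgb, th))  # (50, 60, 10, 10)
#' @export
mapToThermal <- function(roi, pair) {
  if (roi@frame != "rgb")
    stop("geometry error: mapToThermal expects a rect in the rgb frame")
  dt <- frameDim(pair@thermal)
  x0 <- floor(roi@x0 * pair@scaleX)
  y0 <- floor(roi@y0 * pair@scaleY)
  w <- max(1, .roundHalfUp(roi@w * pair@scaleX))
  h <- max(1, .roundHalfUp(roi@h * pair@scaleY))
  x0 <- min(x0, dt[2] - 1L)
  y0 <- min(y0, dt[1] - 1L)
  w <- min(w, dt[2] - x0)
  h <- min(h, dt[1] - y0)
  rect2d(x0, y0, w, h, frame = "thermal")
}

#' Extract the temperatures under a thermal-frame rectangle
#'
#' @param frame a [ThermalFrame-class].
#' @param roi [Rect-class] with `frame == "thermal"`, fully inside the frame.
#' @return the `h x w` temperature sub-matrix (a copy).
#' @export
extractRoi <- function(frame, roi) {
  if (roi@frame != "thermal")
    stop("geometry error: extractRoi expects a rect in the thermal frame")
  d <- frameDim(frame)
  if (roi@x0 + roi@w > d[2] || roi@y0 + roi@h > d[1])
    stop("geometry error: roi [", roi@x0, ",", roi@x0 + roi@w, ") x [",
         roi@y0, ",", roi@y0 + roi@h, ") exceeds frame ", d[2], " x ", d[1])
  temps(frame)[(roi@y0 + 1L):(roi@y0 + roi@h),
               (roi@x0 + 1L):(roi@x0 + roi@w), drop = FALSE]
}

#' Read ROI pair definitions from a JSON config
#'
#' Accepts a single object or a list of objects of the form
#' `{"roi1": {"x0":, "y0":, "w":, "h":}, "axis_x":, "frame": "rgb"}`;
#' patients with a double spinal curve contribute two pairs. ROI #2 is
#' constructed by reflection about the backbone axis.
#'
#' @param path JSON file path.
#' @param frameWidth optional frame width for bounds checking.
#' @return a list of [RoiPair-class] objects.
#' @export
readRoiConfig <- function(path, frameWidth = NULL) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(cfg$roi1) || !is.null(cfg$axis_x)) cfg <- list(cfg)
  lapply(cfg, function(entry) {
    r <- entry$roi1
    if (is.null(r) || is.null(entry$axis_x))
      stop("format error in ", path, ": each entry needs roi1 and axis_x")
    roi1 <- rect2d(r$x0, r$y0, r$w, r$h,
                   frame = if (!is.null(entry$frame)) entry$frame else "rgb")
    roiPair(roi1, entry$axis_x, frameWidth = frameWidth)
  })
}

# map a whole RoiPair onto the thermal grid; mirror ROIs always map to rects
# of identical extent because w, h are shared before scaling
.mapPairToThermal <- function(rois, pair) {
  list(roi1 = mapToThermal(rois@roi1, pair),
       roi2 = mapToThermal(rois@roi2, pair))
}
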