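## Image and calibration I/O.
##
## Canonical on-disk thermal format: a comma-separated text matrix of
## temperatures in degrees C, one image row per line, with an optional JSON
## metadata sidecar (<name>.calib.json). A 16-bit single-channel PNG/TIFF with
## an affine calibration sidecar (temperature = offset + scale * count) is
## accepted as a second dialect.

.sidecarPath <- function(path) {
  sub("\\.[A-Za-z0-9]+$", ".calib.json", path)
}

.readSidecar <- function(path) {
  sc <- .sidecarPath(path)
  if (file.exists(sc)) jsonlite::fromJSON(sc) else NULL
}

#' Read a thermal frame from disk
#'
#' Reads either a delimited-text matrix of temperatures in degrees C (the
#' canonical format) or a 16-bit single-channel PNG/TIFF of raw counts, which
#' requires an affine calibration (`temperature = offset + scale * count`)
#' from the `calibration` argument or from a `<name>.calib.json` sidecar.
#' Metadata (emissivity, ambient temperature, distance, quantisation step) is
#' populated from the sidecar when present, else from defaults.
#'
#' @param path path to a `.csv`/`.txt` temperature matrix or a 16-bit
#'   `.png`/`.tif`/`.tiff` count image.
#' @param calibration `NULL`, or a list with elements `offset` (degrees C) and
#'   `scale` (degrees C per count); required for count-image input when no
#'   sidecar provides `offset_c`/`scale_c_per_count`.
#' @return a [ThermalFrame-class].
#' @seealso [writeThermal()]
#' @export
readThermal <- function(path, calibration = NULL) {
  if (!file.exists(path)) stop("cannot read thermal file: ", path)
  meta <- .readSidecar(path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("png", "tif", "tiff")) {
    img <- if (ext == "png") png::readPNG(path) else
      tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] > 1L)
        stop("format error in ", path, ": expected a single-channel image")
      img <- img[, , 1L]
    }
    # readPNG scales samples to [0,1] by 2^depth - 1 (depth from the IHDR
    # header byte); readTIFF(as.is) keeps raw counts
    counts <- if (ext == "png") {
      depth <- as.integer(readBin(path, "raw", 25)[25])
      round(img * (2^depth - 1))
    } else img
    offset <- if (!is.null(calibration)) calibration$offset else meta$offset_c
    scale <- if (!is.null(calibration)) calibration$scale else
      meta$scale_c_per_count
    if (is.null(offset) || is.null(scale))
      stop("format error in ", path,
           ": count-image input needs an offset/scale calibration")
    t <- offset + scale * counts
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("format error in ", path, ": empty file")
    rows <- strsplit(lines, ",", fixed = TRUE)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop("format error in ", path, ": ragged rows (row ",
           which(widths != widths[1])[1], " has ",
           widths[which(widths != widths[1])[1]], " cells, expected ",
           widths[1], ")")
    vals <- suppressWarnings(lapply(rows, as.numeric))
    for (i in seq_along(vals)) {
      bad <- which(is.na(vals[[i]]))
      if (length(bad))
        stop("format error in ", path, ": non-numeric cell at row ", i,
             ", column ", bad[1])
    }
    t <- do.call(rbind, vals)
    if (!is.null(calibration))
      t <- calibration$offset + calibration$scale * t
  }
  thermalFrame(t,
    emissivity = if (!is.null(meta$emissivity)) meta$emissivity else 0.97,
    ambientC = if (!is.null(meta$ambient_c)) meta$ambient_c else NA_real_,
    distanceM = if (!is.null(meta$distance_m)) meta$distance_m else NA_real_,
    quantizationC = if (!is.null(meta$quantization_c)) meta$quantization_c
      else NA_real_)
}

#' Write a thermal frame as a delimited-text matrix
#'
#' Writes the temperatures as comma-separated text, one image row per line, at
#' full double precision, plus a JSON metadata sidecar. Round-tripping through
#' [readThermal()] reproduces the temperatures to well below 1e-6 degrees C.
#'
#' @param frame a [ThermalFrame-class].
#' @param path output path (`.csv`).
#' @return `path`, invisibly.
#' @export
writeThermal <- function(frame, path) {
  t <- temps(frame)
  lines <- apply(t, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(lines, path)
  jsonlite::write_json(frameMeta(frame), .sidecarPath(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a visual (RGB) frame
#'
#' Reads a standard PNG, JPEG or TIFF image into a three-channel intensity
#' grid in [0, 255]; grayscale sources are replicated across channels and an
#' alpha channel, if present, is dropped.
#'
#' @param path image path.
#' @return an [RgbFrame-class].
#' @export
readRgb <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  img <- tryCatch(switch(ext,
      png = png::readPNG(path),
      jpg = , jpeg = jpeg::readJPEG(path),
      tif = , tiff = tiff::readTIFF(path),
      stop("unsupported image format: .", ext)),
    error = function(e) stop("I/O error reading ", path, ": ",
                             conditionMessage(e)))
  if (is.matrix(img))
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  else if (dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  else if (dim(img)[3] < 3L)
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  rgbFrame(img * 255)
}

#' Write an RgbFrame as PNG
#'
#' @param frame an [RgbFrame-class].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeRgb <- function(frame, path) {
  png::writePNG(frame@channels / 255, path)
  invisible(path)
}

#' Couple an RGB frame with its thermal frame
#'
#' Computes the anisotropic scale factors (thermal / RGB) and returns the
#' registered pair. The two frames are assumed co-registered up to pure
#' scaling by the capture device; aspect ratios differing by more than 1
#' percent are rejected as a registration error.
#'
#' @param rgb an [RgbFrame-class].
#' @param thermal a [ThermalFrame-class].
#' @return an [ImagePair-class].
#' @examples
#' rgb <- rgbFrame(matrix(128, 1080, 1440))
#' th <- thermalFrame(matrix(33, 120, 160))
#' makePair(rgb, th)   # scale 1/9, 1/9
#' @export
makePair <- function(rgb, thermal) {
  dr <- frameDim(rgb)
  dt <- frameDim(thermal)
  sx <- dt[2] / dr[2]
  sy <- dt[1] / dr[1]
  if (abs(sx / sy - 1) > 0.01)
    stop("registration error: rgb and thermal aspect ratios differ by ",
         sprintf("%.1f%%", 100 * abs(sx / sy - 1)),
         " (scale_x = ", signif(sx, 6), ", scale_y = ", signif(sy, 6), ")")
  new("ImagePair", rgb = rgb, thermal = thermal, scaleX = sx, scaleY = sy)
}
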