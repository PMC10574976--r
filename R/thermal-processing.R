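## Grayscale conversion, N x M partitioning and per-subregion averaging:
## turns the two thermal ROIs into the two length-L vectors the decision
## statistic compares.

#' Jointly normalise a ROI pair to grayscale
#'
#' Maps both temperature grids affinely to [0, 1] using the joint minimum and
#' maximum over *both* grids: `g = (T - Tmin) / (Tmax - Tmin)`, so white is
#' the warmest pixel of the pair and black the coldest. Joint (rather than
#' per-ROI) normalisation preserves the between-ROI temperature ordering that
#' the decision rule relies on; it also makes the result invariant to any
#' constant temperature offset applied to both ROIs. When the joint range is
#' zero (both grids constant at one value) every pixel maps to 0.5, which
#' keeps the downstream statistics defined and leads to an inadequate call.
#'
#' @param roiA,roiB numeric temperature matrices (degrees C), non-empty.
#' @return list of two [GrayRoi-class] objects, in input order.
#' @examples
#' g <- toGrayscaleJoint(matrix(c(30, 31), 1), matrix(c(32, 33), 1))
#' g[[1]]@values   # 0, 1/3
#' @export
toGrayscaleJoint <- function(roiA, roiB) {
  if (!length(roiA) || !length(roiB))
    stop("both ROI grids must be non-empty")
  tmin <- min(roiA, roiB)
  tmax <- max(roiA, roiB)
  if (tmax == tmin) {
    ga <- array(0.5, dim(roiA))
    gb <- array(0.5, dim(roiB))
  } else {
    ga <- (roiA - tmin) / (tmax - tmin)
    gb <- (roiB - tmin) / (tmax - tmin)
  }
  list(new("GrayRoi", values = ga, sourceMinC = tmin, sourceMaxC = tmax),
       new("GrayRoi", values = gb, sourceMinC = tmin, sourceMaxC = tmax))
}

# balanced-remainder band sizes: the first (len mod n) bands get the extra row
.bandSizes <- function(len, n) {
  base <- len %/% n
  extra <- len %% n
  c(rep(base + 1L, extra), rep(base, n - extra))
}

#' Partition a grayscale ROI into N x M subregions
#'
#' Slices the ROI into `nRows` horizontal and `nCols` vertical bands. When a
#' dimension does not divide evenly the remainder is balanced: the first
#' `h mod N` row bands get one extra row (analogously for columns), so the
#' subregions tile the ROI exactly. Blocks are returned in row-major order.
#'
#' @param gray a [GrayRoi-class] (or a bare numeric matrix).
#' @param nRows,nCols number of horizontal (N) and vertical (M) slices; each
#'   must not exceed the corresponding grid dimension.
#' @return list of `nRows * nCols` numeric matrices.
#' @export
partitionRoi <- function(gray, nRows, nCols) {
  v <- if (is(gray, "GrayRoi")) gray@values else gray
  h <- nrow(v); w <- ncol(v)
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (nRows < 1L || nCols < 1L || nRows > h || nCols > w)
    stop("partition error: ", nRows, " x ", nCols,
         " subregions requested for a ", h, " x ", w, " grid")
  rb <- .bandSizes(h, nRows)
  cb <- .bandSizes(w, nCols)
  rEnd <- cumsum(rb); rStart <- rEnd - rb + 1L
  cEnd <- cumsum(cb); cStart <- cEnd - cb + 1L
  blocks <- vector("list", nRows * nCols)
  k <- 0L
  for (i in seq_len(nRows)) for (j in seq_len(nCols)) {
    k <- k + 1L
    blocks[[k]] <- v[rStart[i]:rEnd[i], cStart[j]:cEnd[j], drop = FALSE]
  }
  blocks
}

#' Average each subregion into a partition vector
#'
#' Entry k is the arithmetic mean of block k, in the row-major order produced
#' by [partitionRoi()].
#'
#' @param blocks list of numeric matrices (the subregions).
#' @param nRows,nCols the partition counts the blocks came from; inferred as
#'   `length(blocks) x 1` when omitted.
#' @return a [PartitionVector-class].
#' @export
partitionMeans <- function(blocks, nRows = length(blocks), nCols = 1L) {
  if (!length(blocks)) stop("partition error: no blocks")
  if (any(vapply(blocks, length, 1L) == 0L))
    stop("partition error: empty block")
  new("PartitionVector",
      means = vapply(blocks, function(b) mean(b), numeric(1)),
      nRows = as.integer(nRows), nCols = as.integer(nCols))
}

#' ROI pair to the two partition vectors
#'
#' Convenience composition of [toGrayscaleJoint()], [partitionRoi()] and
#' [partitionMeans()] for a pair of temperature grids.
#'
#' @param roiA,roiB numeric temperature matrices.
#' @param nRows,nCols partition counts (default 4 x 4, giving L = 16).
#' @return list of two [PartitionVector-class] objects.
#' @export
partitionPair <- function(roiA, roiB, nRows = 4, nCols = 4) {
  g <- toGrayscaleJoint(roiA, roiB)
  lapply(g, function(gr)
    partitionMeans(partitionRoi(gr, nRows, nCols), nRows, nCols))
}
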