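#' @include AllClasses.R
NULL

#' Accumulate overlapping patch predictions
#'
#' Adds each raster-ordered patch prediction into a per-pixel probability
#' sum (`fullPro`) and visit count (`fullSum`) at its tile position, in
#' double precision.
#'
#' @param preds array (patchH x patchW x nTotal) of patch probabilities in
#'   `[0, 1]`, in the raster order produced by [extractOverlapPatches()].
#' @param geom a [PatchGeometry-class].
#' @param imgH,imgW size of the image being reconstructed.
#' @return An [AccumulatorPair-class].
#' @examples
#' acc <- accumulatePatches(array(1, c(2, 2, 9)), PatchGeometry(2, 2, 1, 1),
#'                          4, 4)
#' @export
accumulatePatches <- function(preds, geom, imgH, imgW) {
  stopifnot(is(geom, "PatchGeometry"))
  if (is(preds, "PatchSet")) preds <- preds@patches
  cnt <- countOverlapPatches(imgH, imgW, geom)
  if (dim(preds)[3] != cnt$nTotal)
    stop("tiling mismatch: ", dim(preds)[3], " patches given, ",
         cnt$nTotal, " expected for ", imgH, " x ", imgW)
  if (min(preds) < 0 || max(preds) > 1)
    stop("invalid probability: predictions must lie in [0, 1]")
  acc <- cpp_accumulate(preds, imgH, imgW, geom@patchH, geom@patchW,
                        geom@strideH, geom@strideW)
  new("AccumulatorPair", fullPro = acc$full_pro, fullSum = acc$full_sum)
}

#' Average accumulated predictions into a probability map
#'
#' Divides the per-pixel probability sum by the visit count wherever at
#' least one patch visited; uncovered pixels (the floor-tiling remainder)
#' are assigned probability 0 and flagged in the coverage mask.
#'
#' @param acc an [AccumulatorPair-class].
#' @return A [ProbabilityMap-class].
#' @export
finalizeAccumulator <- function(acc) {
  stopifnot(is(acc, "AccumulatorPair"))
  covered <- acc@fullSum > 0
  values <- matrix(0, nrow(acc@fullPro), ncol(acc@fullPro))
  values[covered] <- acc@fullPro[covered] / acc@fullSum[covered]
  new("ProbabilityMap", values = values, coverage = covered)
}

#' Reconstruct a probability map from overlapping patch predictions
#'
#' Composition of [accumulatePatches()] and [finalizeAccumulator()]: the
#' frequency-weighted average of all overlapping patch predictions.
#'
#' @inheritParams accumulatePatches
#' @return A [ProbabilityMap-class].
#' @examples
#' g <- PatchGeometry(2, 2, 1, 1)
#' p <- reconstructMap(array(0.5, c(2, 2, 9)), g, 4, 4)
#' @export
reconstructMap <- function(preds, geom, imgH, imgW) {
  finalizeAccumulator(accumulatePatches(preds, geom, imgH, imgW))
}

#' Write a probability map to disk
#'
#' Writes an 8-bit grayscale PNG (`round(255 * p)`) for inspection and a
#' lossless float dump (binary little-endian doubles with a small text
#' header) for exact downstream evaluation.
#'
#' @param pmap a [ProbabilityMap-class].
#' @param pngPath path of the 8-bit PNG (NULL to skip).
#' @param binPath path of the lossless dump (NULL to skip).
#' @return invisibly, the paths written.
#' @export
writeProbabilityMap <- function(pmap, pngPath = NULL, binPath = NULL) {
  stopifnot(is(pmap, "ProbabilityMap"))
  if (!is.null(pngPath))
    writeImageRaster(round(255 * pmap@values) / 255, pngPath)
  if (!is.null(binPath)) {
    con <- file(binPath, "wb")
    on.exit(close(con))
    writeBin(as.integer(dim(pmap@values)), con, size = 4, endian = "little")
    writeBin(as.vector(pmap@values), con, size = 8, endian = "little")
    writeBin(as.integer(pmap@coverage), con, size = 4, endian = "little")
  }
  invisible(c(pngPath, binPath))
}

#' Read a lossless probability-map dump
#'
#' @param binPath path written by [writeProbabilityMap()].
#' @return A [ProbabilityMap-class].
#' @export
readProbabilityMap <- function(binPath) {
  con <- file(binPath, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", 2, size = 4, endian = "little")
  v <- readBin(con, "double", prod(d), size = 8, endian = "little")
  cov <- readBin(con, "integer", prod(d), size = 4, endian = "little")
  new("ProbabilityMap", values = matrix(v, d[1], d[2]),
      coverage = matrix(cov == 1L, d[1], d[2]))
}
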