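#' @include AllClasses.R
NULL

# ITU-R BT.601 luminance weights
.LUMA <- c(0.299, 0.587, 0.114)

#' Convert a color image to grayscale
#'
#' Collapses an H x W x 3 array to a single channel. The default is the
#' BT.601 luminance combination `0.299 R + 0.587 G + 0.114 B`; the
#' `"green"` mode extracts the green channel, a common choice for fundus
#' photographs where vessels have the strongest contrast in green.
#' A matrix (already grayscale) passes through unchanged.
#'
#' @param image numeric matrix or H x W x 3 array, finite intensities.
#' @param mode `"luminance"` or `"green"`.
#' @return H x W numeric matrix.
#' @examples
#' img <- array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3))
#' g <- toGrayscale(img)
#' @export
toGrayscale <- function(image, mode = c("luminance", "green")) {
  mode <- match.arg(mode)
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3L && d[3] == 1L) return(image[, , 1])
  if (length(d) != 3L || d[3] != 3L)
    stop("image must have 1 or 3 channels, got dim ",
         paste(d, collapse = " x "))
  if (!all(is.finite(image))) stop("image intensities must be finite")
  if (mode == "green") return(image[, , 2])
  .LUMA[1] * image[, , 1] + .LUMA[2] * image[, , 2] + .LUMA[3] * image[, , 3]
}

#' Pooled intensity statistics of a training set
#'
#' Computes the mean and population standard deviation over every pixel of
#' every image in the list, the dataset-level moments with which both
#' training and test images are standardized.
#'
#' @param images list of grayscale matrices.
#' @return A [NormalizationStats-class] object.
#' @examples
#' computeDatasetStats(list(matrix(0, 1, 2), matrix(2, 1, 2)))
#' @export
computeDatasetStats <- function(images) {
  if (!length(images)) stop("need at least one image")
  n <- sum(vapply(images, length, 0))
  s <- sum(vapply(images, sum, 0))
  mu <- s / n
  ss <- sum(vapply(images, function(x) sum((x - mu)^2), 0))
  sigma <- sqrt(ss / n)
  if (sigma <= 0)
    stop("degenerate statistics: all pixels identical (zero variance)")
  NormalizationStats(mu, sigma)
}

#' Standardize an image with dataset statistics
#'
#' @param image grayscale matrix.
#' @param stats a [NormalizationStats-class], typically computed once from
#'   the training split and reused for test images.
#' @return matrix `(image - mu) / sigma`.
#' @examples
#' normalizeImage(matrix(5, 2, 2), NormalizationStats(5, 2))
#' @export
normalizeImage <- function(image, stats) {
  stopifnot(is(stats, "NormalizationStats"))
  (image - stats@mu) / stats@sigma
}
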