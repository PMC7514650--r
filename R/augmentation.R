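#' @include AllClasses.R
NULL

.gaussianKernel <- function(sigma, maxR = Inf) {
  r <- min(max(1L, ceiling(3 * sigma)), maxR)
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  outer(k, k)
}

#' Draw a random elastic displacement field
#'
#' Raw per-pixel displacements are uniform in `[-1, 1]`
#' (`U(x, y) = rand(-1, +1)`), then smoothed with a Gaussian of scale
#' `sigma` and scaled by the amplitude `alpha` (both in pixels), giving a
#' smooth random warp in the style of elastic distortions for handwriting
#' and medical images.
#'
#' @param shape length-2 integer (rows, cols).
#' @param sigma Gaussian smoothing scale in pixels (> 0).
#' @param alpha displacement amplitude in pixels (>= 0).
#' @return list with matrices `uRow`, `uCol` (the smoothed, scaled field),
#'   `rawRow`, `rawCol` (the uniform draws), and `sigma`, `alpha`.
#' @examples
#' f <- randomDisplacementField(c(48, 48), sigma = 4, alpha = 8)
#' @export
randomDisplacementField <- function(shape, sigma = 4, alpha = 8) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  h <- shape[1]; w <- shape[2]
  rawRow <- matrix(runif(h * w, -1, 1), h, w)
  rawCol <- matrix(runif(h * w, -1, 1), h, w)
  if (alpha == 0) {
    uRow <- uCol <- matrix(0, h, w)
  } else {
    # kernel support is capped so it never exceeds the patch
    k <- .gaussianKernel(sigma, maxR = (min(h, w) - 1L) %/% 2L)
    uRow <- alpha * EBImage::filter2(rawRow, k, boundary = "replicate")
    uCol <- alpha * EBImage::filter2(rawCol, k, boundary = "replicate")
  }
  list(uRow = uRow, uCol = uCol, rawRow = rawRow, rawCol = rawCol,
       sigma = sigma, alpha = alpha)
}

# sample matrix m at fractional coordinates (r, c) with edge replication
.sampleBilinear <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * m[cbind(r0, c0)] + fr * (1 - fc) * m[cbind(r1, c0)] +
    (1 - fr) * fc * m[cbind(r0, c1)] + fr * fc * m[cbind(r1, c1)]
}

.sampleNearest <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  m[cbind(pmin(pmax(round(r), 1), H), pmin(pmax(round(c), 1), W))]
}

#' Warp an image/ground-truth patch pair with a displacement field
#'
#' The intensity patch is resampled with bilinear interpolation, the label
#' patch with nearest-neighbor so it stays strictly binary; out-of-bounds
#' samples replicate the edge.
#'
#' @param imagePatch numeric matrix.
#' @param gtPatch binary matrix, same size.
#' @param field displacement field from [randomDisplacementField()], same
#'   size.
#' @return list with `image` and `gt`.
#' @export
applyDeformation <- function(imagePatch, gtPatch, field) {
  if (!identical(dim(imagePatch), dim(gtPatch)) ||
      !identical(dim(imagePatch), dim(field$uRow)))
    stop("patches and field must share the same shape")
  H <- nrow(imagePatch); W <- ncol(imagePatch)
  grid <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
  r <- grid[, 1] + as.vector(field$uRow)
  c <- grid[, 2] + as.vector(field$uCol)
  list(image = matrix(as.numeric(.sampleBilinear(imagePatch, r, c)), H, W),
       gt = matrix(as.numeric(.sampleNearest(gtPatch, r, c)), H, W))
}

#' Double a patch set with elastic deformations
#'
#' Returns the originals followed by one independently deformed copy of
#' each, so a training set of n patch pairs becomes 2n — the fixed
#' "real + augmented" offline design.
#'
#' @param source,ground aligned [PatchSet-class] objects.
#' @param sigma,alpha displacement-field parameters (pixels).
#' @return list of doubled [PatchSet-class] objects `source`, `ground`.
#' @export
augmentPatchSet <- function(source, ground, sigma = 4, alpha = 8) {
  stopifnot(is(source, "PatchSet"), is(ground, "PatchSet"))
  if (!identical(dim(source@patches), dim(ground@patches)))
    stop("misaligned patch sets")
  d <- dim(source@patches)
  n <- d[3]
  src <- array(0, c(d[1], d[2], 2L * n))
  gnd <- array(0, c(d[1], d[2], 2L * n))
  src[, , seq_len(n)] <- source@patches
  gnd[, , seq_len(n)] <- ground@patches
  for (i in seq_len(n)) {
    f <- randomDisplacementField(c(d[1], d[2]), sigma, alpha)
    w <- applyDeformation(source@patches[, , i], ground@patches[, , i], f)
    src[, , n + i] <- w$image
    gnd[, , n + i] <- w$gt
  }
  centers <- rbind(source@centers, source@centers)
  list(source = PatchSet(src, centers, source@sourceId, "random"),
       ground = PatchSet(gnd, centers, ground@sourceId, "random"))
}
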