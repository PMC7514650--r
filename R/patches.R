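#' @include AllClasses.R
NULL

#' Patches per image under equal distribution
#'
#' Splits a total patch budget evenly across images, flooring when the
#' total is not divisible and warning about the shortfall.
#'
#' @param nTotal total number of patches requested.
#' @param nImages number of training images.
#' @return integer patches per image.
#' @examples
#' patchesPerImage(40000, 20) # 2000
#' @export
patchesPerImage <- function(nTotal, nImages) {
  stopifnot(nTotal >= nImages, nImages >= 1)
  k <- nTotal %/% nImages
  if (nTotal %% nImages != 0)
    warning(sprintf("%d patches not divisible by %d images; using %d per image (%d total)",
                    nTotal, nImages, k, k * nImages))
  as.integer(k)
}

#' Is a patch center inside the field of view?
#'
#' @param center length-2 integer vector, 1-based (row, col).
#' @param fov binary matrix.
#' @return TRUE iff `fov[row, col] == 1`.
#' @examples
#' centerInFov(c(1, 1), matrix(1, 2, 2))
#' @export
centerInFov <- function(center, fov) {
  r <- center[1]; c <- center[2]
  if (r < 1 || r > nrow(fov) || c < 1 || c > ncol(fov))
    stop("center (", r, ", ", c, ") outside image bounds")
  fov[r, c] == 1
}

# admissible center range so the patch lies fully inside the image:
# top = center - floor(ph/2) >= 1 and top + ph - 1 <= H
.centerRange <- function(imgLen, patchLen) {
  half <- patchLen %/% 2L
  c(1L + half, imgLen - patchLen + 1L + half)
}

.cropAt <- function(m, center, ph, pw) {
  top <- center[1] - ph %/% 2L
  left <- center[2] - pw %/% 2L
  m[top:(top + ph - 1L), left:(left + pw - 1L)]
}

#' Sample random FOV-constrained training patches
#'
#' Draws `n` patch centers uniformly, by rejection, from positions whose
#' center lies inside the FOV mask and whose patch lies fully inside the
#' image, then crops pixel-aligned source and ground-truth patches at the
#' accepted centers. Duplicate centers are allowed.
#'
#' @param triplet an [ImageTriplet-class] whose `image` is grayscale
#'   (already converted/normalized).
#' @param n number of patches.
#' @param geom a [PatchGeometry-class].
#' @param maxDrawFactor rejection-loop cap: at most `maxDrawFactor * n`
#'   draws before giving up with an error.
#' @return list with [PatchSet-class] elements `source` and `ground`.
#' @examples
#' tr <- ImageTriplet(matrix(runif(100 * 100), 100), matrix(0, 100, 100),
#'                    matrix(1, 100, 100), "ex")
#' ps <- sampleRandomPatches(tr, 5, PatchGeometry(48, 48, 5, 5))
#' @export
sampleRandomPatches <- function(triplet, n, geom, maxDrawFactor = 10000L) {
  stopifnot(is(triplet, "ImageTriplet"), is(geom, "PatchGeometry"), n >= 1)
  img <- triplet@image
  if (length(dim(img)) != 2L)
    stop("sampleRandomPatches expects a grayscale image; run toGrayscale first")
  ph <- geom@patchH; pw <- geom@patchW
  H <- nrow(img); W <- ncol(img)
  if (H < ph || W < pw) stop("image smaller than patch")
  rr <- .centerRange(H, ph); cc <- .centerRange(W, pw)
  fov <- triplet@fov
  if (!any(fov[rr[1]:rr[2], cc[1]:cc[2]] == 1))
    stop("unsatisfiable sampling: no admissible patch center inside the FOV")
  cap <- maxDrawFactor * n
  centers <- matrix(0L, n, 2)
  src <- array(0, c(ph, pw, n))
  gnd <- array(0, c(ph, pw, n))
  got <- 0L; draws <- 0L
  while (got < n) {
    if (draws >= cap)
      stop("rejection-sampling cap of ", cap, " draws exceeded")
    draws <- draws + 1L
    ctr <- c(sample.int(rr[2] - rr[1] + 1L, 1L) + rr[1] - 1L,
             sample.int(cc[2] - cc[1] + 1L, 1L) + cc[1] - 1L)
    if (!centerInFov(ctr, fov)) next
    got <- got + 1L
    centers[got, ] <- ctr
    src[, , got] <- .cropAt(img, ctr, ph, pw)
    gnd[, , got] <- .cropAt(triplet@groundTruth, ctr, ph, pw)
  }
  list(source = PatchSet(src, centers, triplet@id, "random"),
       ground = PatchSet(gnd, centers, triplet@id, "random"))
}

#' Count overlapping test patches
#'
#' Number of tiles when an image is covered with overlapping patches at a
#' fixed stride: `floor((img - patch)/stride) + 1` per axis, multiplied.
#'
#' @param imgH,imgW image size in pixels.
#' @param geom a [PatchGeometry-class].
#' @return list with `nH`, `nW`, `nTotal`.
#' @examples
#' countOverlapPatches(584, 565, PatchGeometry(48, 48, 5, 5))
#' @export
countOverlapPatches <- function(imgH, imgW, geom) {
  stopifnot(is(geom, "PatchGeometry"))
  if (imgH < geom@patchH || imgW < geom@patchW)
    stop("invalid geometry: image (", imgH, " x ", imgW,
         ") smaller than patch")
  nH <- (imgH - geom@patchH) %/% geom@strideH + 1L
  nW <- (imgW - geom@patchW) %/% geom@strideW + 1L
  list(nH = as.integer(nH), nW = as.integer(nW),
       nTotal = as.integer(nH * nW))
}

#' Extract overlapping patches in raster order
#'
#' Deterministic tiling for inference: patch (i, j) has its top-left corner
#' at `((i-1) * strideH + 1, (j-1) * strideW + 1)`, enumerated rows outer,
#' columns inner. When the strides do not divide the margins exactly the
#' right/bottom remainder is left uncovered (handled at reconstruction);
#' `padToCover = TRUE` reflect-pads the image first so every pixel is
#' covered, and reports the padded size.
#'
#' @param image grayscale matrix.
#' @param geom a [PatchGeometry-class].
#' @param padToCover reflect-pad so tiling covers the whole image.
#' @return a [PatchSet-class] with ordering `"raster"`; when padding, the
#'   attribute `paddedDim` records the padded image size.
#' @examples
#' ps <- extractOverlapPatches(matrix(1:16, 4), PatchGeometry(2, 2, 2, 2))
#' @export
extractOverlapPatches <- function(image, geom, padToCover = FALSE) {
  ph <- geom@patchH; pw <- geom@patchW
  if (padToCover) {
    cov <- .coveredExtent(nrow(image), ncol(image), geom)
    addH <- nrow(image) - cov[1]; addW <- ncol(image) - cov[2]
    if (addH > 0) {
      padH <- geom@strideH * ceiling(addH / geom@strideH)
      image <- rbind(image, image[nrow(image) - seq_len(padH) + 1L, , drop = FALSE])
    }
    if (addW > 0) {
      padW <- geom@strideW * ceiling(addW / geom@strideW)
      image <- cbind(image, image[, ncol(image) - seq_len(padW) + 1L, drop = FALSE])
    }
  }
  cnt <- countOverlapPatches(nrow(image), ncol(image), geom)
  patches <- array(0, c(ph, pw, cnt$nTotal))
  centers <- matrix(0L, cnt$nTotal, 2)
  k <- 0L
  for (i in seq_len(cnt$nH)) {
    top <- (i - 1L) * geom@strideH + 1L
    for (j in seq_len(cnt$nW)) {
      left <- (j - 1L) * geom@strideW + 1L
      k <- k + 1L
      patches[, , k] <- image[top:(top + ph - 1L), left:(left + pw - 1L)]
      centers[k, ] <- c(top + ph %/% 2L, left + pw %/% 2L)
    }
  }
  out <- PatchSet(patches, centers, "tiling", "raster")
  if (padToCover) attr(out, "paddedDim") <- dim(image)
  out
}

# extent of the region covered by at least one tile
.coveredExtent <- function(imgH, imgW, geom) {
  cnt <- countOverlapPatches(imgH, imgW, geom)
  c((cnt$nH - 1L) * geom@strideH + geom@patchH,
    (cnt$nW - 1L) * geom@strideW + geom@patchW)
}
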