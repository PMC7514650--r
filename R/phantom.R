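#' @include AllClasses.R
NULL

# stamp a disc of diameter `w` centered at fractional (r, c) into mask
.stampDisc <- function(mask, r, c, w) {
  rad <- w / 2
  lo <- floor(-rad):ceiling(rad)
  rows <- round(r) + lo
  cols <- round(c) + lo
  ok_r <- rows >= 1 & rows <= nrow(mask)
  ok_c <- cols >= 1 & cols <= ncol(mask)
  rows <- rows[ok_r]; cols <- cols[ok_c]
  if (!length(rows) || !length(cols)) return(mask)
  dist2 <- outer((rows - r)^2, (cols - c)^2, "+")
  sel <- dist2 <= rad^2
  if (w <= 1.5) { # guarantee single-pixel vessels leave a trace
    mask[round(r), round(c)] <- 1
  }
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx)) mask[cbind(rows[idx[, 1]], cols[idx[, 2]])] <- 1
  mask
}

# grow one branching random-walk tree into `gt`, stopping when the tree's
# stamped-pixel budget is spent or every branch has left the FOV
.growTree <- function(gt, spec, R, ctr, pixelBudget) {
  H <- nrow(gt); W <- ncol(gt)
  wmin <- spec@widthRange[1]; wmax <- spec@widthRange[2]
  a0 <- runif(1, 0, 2 * pi)
  d0 <- R * sqrt(runif(1, 0, 0.6))
  stack <- list(list(r = ctr[1] + d0 * sin(a0), c = ctr[2] + d0 * cos(a0),
                     heading = runif(1, 0, 2 * pi),
                     width = runif(1, 0.6 * wmax, wmax)))
  placed <- 0L
  maxSteps <- 3L * max(H, W) # per-branch cap
  while (length(stack) && placed < pixelBudget) {
    br <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- br$r; c <- br$c; heading <- br$heading; w <- br$width
    for (s in seq_len(maxSteps)) {
      if ((r - ctr[1])^2 + (c - ctr[2])^2 > R^2) break
      before <- sum(gt)
      gt <- .stampDisc(gt, r, c, w)
      placed <- placed + (sum(gt) - before)
      if (placed >= pixelBudget) break
      heading <- heading + rnorm(1, 0, 0.12) # smooth curvature
      r <- r + sin(heading)
      c <- c + cos(heading)
      w <- max(wmin, w * 0.995) # gentle distal tapering
      if (runif(1) < spec@branchProb && length(stack) < 8) {
        stack[[length(stack) + 1L]] <-
          list(r = r, c = c,
               heading = heading + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
               width = max(wmin, 0.75 * w))
      }
    }
  }
  gt
}

#' Generate one synthetic fundus triplet
#'
#' Draws a branching random-walk vessel tree (per-step heading jitter,
#' stochastic bifurcation, distal width tapering within the configured
#' 1-4 px range) inside a circular FOV, rasterizes it as the binary ground
#' truth, and renders the source image as a smooth background gradient plus
#' the signed vessel contrast (Gaussian-blurred ground truth) plus Gaussian
#' noise, expanded to 3 channels with fundus-like color weights. Tree count
#' is re-tuned automatically until the vessel fraction inside the FOV falls
#' in `[0.05, 0.20]`, bracketing the ~10% vessel prevalence of real fundus
#' images.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the triplet is bit-reproducible.
#' @return An [ImageTriplet-class] with a color (H x W x 3) image.
#' @examples
#' tr <- generatePhantom(PhantomSpec(height = 64, width = 64), seed = 7)
#' @export
generatePhantom <- function(spec, seed = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  if (!is.null(seed)) set.seed(seed)
  H <- spec@height; W <- spec@width
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  R <- spec@fovRadiusFrac * min(H, W) / 2
  fov <- matrix(0, H, W)
  dist2 <- outer((seq_len(H) - ctr[1])^2, (seq_len(W) - ctr[2])^2, "+")
  fov[dist2 <= R^2] <- 1

  # each tree gets an equal share of a target vessel budget near the ~10%
  # prevalence of real fundus images; extra trees are grown if stamping
  # fell short (branches can exit the FOV early)
  fovArea <- sum(fov)
  target <- runif(1, 0.08, 0.14) * fovArea
  gt <- matrix(0, H, W)
  for (t in seq_len(spec@nTrees))
    gt <- .growTree(gt, spec, R, ctr, pixelBudget = target / spec@nTrees * t - sum(gt))
  extra <- 0L
  while (sum(gt * fov) / fovArea < 0.05 && extra < 12L) {
    gt <- .growTree(gt, spec, R, ctr, pixelBudget = target - sum(gt))
    extra <- extra + 1L
  }
  gt <- gt * fov
  frac <- sum(gt) / fovArea
  if (frac < 0.05 || frac > 0.20)
    stop("could not reach a vessel fraction in [0.05, 0.20] after retries")

  # background: base level + smooth linear gradient, dark outside the FOV
  base <- if (spec@contrast < 0) 160 else 50
  gr <- runif(2, -20, 20)
  bg <- base + outer(gr[1] * (seq_len(H) / H - 0.5),
                     gr[2] * (seq_len(W) / W - 0.5), "+")
  vessels <- EBImage::filter2(gt, .gaussianKernel(0.7), boundary = "replicate")
  img <- bg + spec@contrast * vessels +
    matrix(rnorm(H * W, 0, spec@noiseSd), H, W)
  img <- img * fov + 4 * (1 - fov)
  img <- pmin(pmax(img, 0), 255)
  color <- array(0, c(H, W, 3))
  color[, , 1] <- pmin(img * 1.15, 255) # fundus images are strongly red
  color[, , 2] <- img
  color[, , 3] <- img * 0.55
  ImageTriplet(color, gt, fov,
               id = sprintf("phantom_%06d", sample.int(999999L, 1)))
}

#' Generate a dataset of independent phantoms
#'
#' Per-triplet seeds are derived from the master seed, so the whole list is
#' reproducible and each triplet is independent.
#'
#' @param n number of triplets.
#' @param spec a [PhantomSpec-class].
#' @param seed master seed.
#' @return list of [ImageTriplet-class] objects (ids `phantom_001` ...).
#' @export
generatePhantomDataset <- function(n, spec = PhantomSpec(), seed = 1L) {
  if (n == 0) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    tr <- generatePhantom(spec, seed = seeds[i])
    tr@id <- sprintf("phantom_%03d", i)
    tr
  })
}
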