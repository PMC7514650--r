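# Shared in-code fixtures: everything is generated at test time.

# a small grayscale triplet with an all-ones FOV
makeFlatTriplet <- function(h = 100, w = 100, seed = 1) {
  set.seed(seed)
  ImageTriplet(matrix(runif(h * w, 0, 255), h, w),
               matrix(rbinom(h * w, 1, 0.1), h, w),
               matrix(1, h, w), "flat")
}

# circular-FOV triplet
makeDiscTriplet <- function(h = 100, w = 100, seed = 1) {
  set.seed(seed)
  fov <- matrix(0, h, w)
  d2 <- outer((seq_len(h) - (h + 1) / 2)^2, (seq_len(w) - (w + 1) / 2)^2, "+")
  fov[d2 <= (0.45 * min(h, w))^2] <- 1
  ImageTriplet(matrix(runif(h * w, 0, 255), h, w),
               matrix(rbinom(h * w, 1, 0.1), h, w), fov, "disc")
}

# tiny dense U-net configuration for fast structural tests
tinyDenseConfig <- function(dropout = 0) {
  NetworkConfig(growthRate = 4, initChannels = 4, nDenseBlocks = 2,
                layersPerBlock = 2, patchSize = 16, dropout = dropout)
}

# brute-force corner enumeration oracle for the tiling arithmetic
enumerateCorners <- function(imgH, imgW, geom) {
  tops <- seq(1, imgH, by = geom@strideH)
  tops <- tops[tops + geom@patchH - 1 <= imgH]
  lefts <- seq(1, imgW, by = geom@strideW)
  lefts <- lefts[lefts + geom@patchW - 1 <= imgW]
  list(nH = length(tops), nW = length(lefts),
       nTotal = length(tops) * length(lefts), tops = tops, lefts = lefts)
}

# O(n^2) tie-aware pairwise Mann-Whitney oracle
aucPairwise <- function(p, g) {
  pos <- p[g == 1]; neg <- p[g == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

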