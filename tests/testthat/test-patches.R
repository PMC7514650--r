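test_that("patch budget splits evenly with floor and warning", {
  expect_identical(patchesPerImage(40000, 20), 2000L)
  expect_identical(patchesPerImage(10, 10), 1L)
  expect_warning(k <- patchesPerImage(7, 2), "not divisible")
  expect_identical(k, 3L)
  expect_error(patchesPerImage(5, 10))
})

test_that("FOV center test agrees with direct lookup", {
  fov <- matrix(0, 9, 9)
  fov[5, 5] <- 1
  expect_true(centerInFov(c(5, 5), fov))
  expect_false(centerInFov(c(1, 1), fov))
  expect_error(centerInFov(c(0, 5), fov), "bounds")
  expect_error(centerInFov(c(5, 10), fov), "bounds")

  tr <- makeDiscTriplet(60, 60, seed = 4)
  fov <- fovMask(tr)
  set.seed(5)
  for (i in 1:200) {
    ctr <- c(sample(60, 1), sample(60, 1))
    expect_identical(centerInFov(ctr, fov), fov[ctr[1], ctr[2]] == 1)
  }
})

test_that("random patches are FOV-centered, in-bounds, crop-consistent", {
  tr <- makeFlatTriplet(100, 100, seed = 6)
  geom <- PatchGeometry(48, 48, 5, 5)
  set.seed(7)
  ps <- sampleRandomPatches(tr, 5, geom)
  expect_identical(dim(ps$source@patches), c(48L, 48L, 5L))
  img <- sourceImage(tr)
  for (i in 1:5) {
    ctr <- ps$source@centers[i, ]
    top <- ctr[1] - 24L; left <- ctr[2] - 24L
    expect_gte(top, 1); expect_lte(top + 47, 100)
    expect_equal(ps$source@patches[, , i],
                 img[top:(top + 47), left:(left + 47)])
    expect_equal(ps$ground@patches[, , i],
                 groundTruth(tr)[top:(top + 47), left:(left + 47)])
  }
  expect_true(all(ps$ground@patches %in% c(0, 1)))
})

test_that("sampling fails cleanly on an empty FOV and respects the cap", {
  tr <- makeFlatTriplet(60, 60, seed = 8)
  tr@fov[] <- 0
  expect_error(sampleRandomPatches(tr, 3, PatchGeometry(16, 16, 4, 4)),
               "unsatisfiable")
  # FOV admissible only outside the clamped center range -> cap error
  tr2 <- makeFlatTriplet(60, 60, seed = 8)
  tr2@fov[] <- 0
  tr2@fov[1, 1] <- 1
  expect_error(sampleRandomPatches(tr2, 1, PatchGeometry(16, 16, 4, 4)),
               "unsatisfiable|cap")
})

test_that("random sampling is bit-reproducible under a fixed seed", {
  tr <- makeDiscTriplet(80, 80, seed = 9)
  geom <- PatchGeometry(32, 32, 5, 5)
  set.seed(123)
  a <- sampleRandomPatches(tr, 20, geom)
  set.seed(123)
  b <- sampleRandomPatches(tr, 20, geom)
  expect_identical(a$source@centers, b$source@centers)
  expect_identical(a$source@patches, b$source@patches)
})

test_that("tile counts follow the floor formula and match enumeration", {
  g <- PatchGeometry(48, 48, 5, 5)
  expect_identical(countOverlapPatches(48, 48, g)$nTotal, 1L)

  drive <- countOverlapPatches(584, 565, g)
  oracle <- enumerateCorners(584, 565, g)
  expect_identical(drive$nH, oracle$nH)
  expect_identical(drive$nW, oracle$nW)
  expect_identical(drive$nTotal, oracle$nTotal)

  expect_error(countOverlapPatches(40, 60, g), "smaller than patch")

  set.seed(14)
  for (i in 1:200) {
    ph <- sample(2:12, 1); pw <- sample(2:12, 1)
    geom <- PatchGeometry(ph, pw, sample(ph, 1), sample(pw, 1))
    ih <- ph + sample(0:30, 1); iw <- pw + sample(0:30, 1)
    expect_identical(countOverlapPatches(ih, iw, geom)$nTotal,
                     enumerateCorners(ih, iw, geom)$nTotal)
  }
})

test_that("raster extraction crops at stride offsets in row-major order", {
  img <- matrix(1:16, 4, 4)
  ps <- extractOverlapPatches(img, PatchGeometry(2, 2, 2, 2))
  expect_identical(dim(ps@patches)[3], 4L)
  expect_equal(ps@patches[, , 1], img[1:2, 1:2])
  expect_equal(ps@patches[, , 2], img[1:2, 3:4]) # columns inner
  expect_equal(ps@patches[, , 3], img[3:4, 1:2])
  expect_equal(ps@patches[, , 4], img[3:4, 3:4])

  set.seed(15)
  img <- matrix(runif(25), 5, 5)
  ps <- extractOverlapPatches(img, PatchGeometry(3, 3, 2, 2))
  expect_identical(dim(ps@patches)[3], 4L)
  k <- 0
  for (top in c(1, 3)) for (left in c(1, 3)) {
    k <- k + 1
    expect_equal(ps@patches[, , k], img[top:(top + 2), left:(left + 2)])
  }

  const <- matrix(3.5, 7, 9)
  ps <- extractOverlapPatches(const, PatchGeometry(4, 4, 2, 3))
  expect_true(all(ps@patches == 3.5))
})

test_that("tiling covers exactly the analytic region; remainder uncovered", {
  set.seed(16)
  for (i in 1:25) {
    ph <- sample(3:8, 1)
    geom <- PatchGeometry(ph, ph, sample(ph, 1), sample(ph, 1))
    ih <- ph + sample(0:15, 1); iw <- ph + sample(0:15, 1)
    cnt <- countOverlapPatches(ih, iw, geom)
    visits <- matrix(0, ih, iw)
    for (a in seq_len(cnt$nH)) for (b in seq_len(cnt$nW)) {
      top <- (a - 1) * geom@strideH + 1
      left <- (b - 1) * geom@strideW + 1
      visits[top:(top + ph - 1), left:(left + ph - 1)] <-
        visits[top:(top + ph - 1), left:(left + ph - 1)] + 1
    }
    covH <- (cnt$nH - 1) * geom@strideH + ph
    covW <- (cnt$nW - 1) * geom@strideW + ph
    expect_true(all(visits[seq_len(covH), seq_len(covW)] >= 1))
    if (covH < ih) expect_true(all(visits[(covH + 1):ih, ] == 0))
    if (covW < iw) expect_true(all(visits[, (covW + 1):iw] == 0))
  }
})

test_that("pad-to-cover mode tiles the whole image", {
  img <- matrix(runif(50 * 47), 50, 47)
  geom <- PatchGeometry(16, 16, 6, 6)
  ps <- extractOverlapPatches(img, geom, padToCover = TRUE)
  pd <- attr(ps, "paddedDim")
  cov <- DenseVessel:::.coveredExtent(pd[1], pd[2], geom)
  expect_gte(cov[1], 50)
  expect_gte(cov[2], 47)
})

test_that("geometry validity is enforced", {
  expect_error(PatchGeometry(4, 4, 5, 4), "stride")
  expect_error(PatchGeometry(0, 4, 1, 1), ">= 1")
})
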