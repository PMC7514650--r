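test_that("displacement fields are bounded, smoothed and seeded", {
  set.seed(30)
  f <- randomDisplacementField(c(48, 48), sigma = 4, alpha = 8)
  expect_true(all(f$rawRow >= -1 & f$rawRow <= 1))
  expect_true(all(f$rawCol >= -1 & f$rawCol <= 1))
  # smoothing gain <= 1, so |u| <= alpha
  expect_lte(max(abs(f$uRow)), 8)
  expect_lte(max(abs(f$uCol)), 8)

  set.seed(31)
  a <- randomDisplacementField(c(24, 24), 4, 8)
  set.seed(31)
  b <- randomDisplacementField(c(24, 24), 4, 8)
  expect_identical(a$uRow, b$uRow)

  z <- randomDisplacementField(c(8, 8), 4, 0)
  expect_true(all(z$uRow == 0) && all(z$uCol == 0))
  expect_error(randomDisplacementField(c(8, 8), 0, 8), "sigma")
})

test_that("warping is identity under a zero field, binary-safe otherwise", {
  set.seed(32)
  img <- matrix(runif(24 * 24), 24, 24)
  gt <- matrix(rbinom(24 * 24, 1, 0.2), 24, 24)
  zf <- randomDisplacementField(c(24, 24), 4, 0)
  w <- applyDeformation(img, gt, zf)
  expect_equal(w$image, img, tolerance = 1e-12)
  expect_identical(w$gt, matrix(as.numeric(gt), 24, 24))

  f <- randomDisplacementField(c(24, 24), 4, 8)
  w <- applyDeformation(img, gt, f)
  expect_true(all(w$gt %in% c(0, 1)))

  const <- matrix(2.5, 24, 24)
  w <- applyDeformation(const, gt, f)
  expect_true(all(abs(w$image - 2.5) < 1e-6))

  expect_error(applyDeformation(img, gt[1:10, 1:10], f), "shape")
})

test_that("augmentation doubles the set, preserving originals first", {
  set.seed(33)
  src <- PatchSet(array(runif(16 * 16 * 3), c(16, 16, 3)),
                  matrix(1L, 3, 2))
  gnd <- PatchSet(array(as.numeric(rbinom(16 * 16 * 3, 1, 0.15)),
                        c(16, 16, 3)), matrix(1L, 3, 2))
  out <- augmentPatchSet(src, gnd)
  expect_identical(dim(out$source@patches)[3], 6L)
  expect_identical(out$source@patches[, , 1:3], src@patches)
  expect_identical(out$ground@patches[, , 1:3], gnd@patches)
  expect_true(all(out$ground@patches %in% c(0, 1)))
  # deformed copies differ from originals
  expect_gt(max(abs(out$source@patches[, , 4:6] - src@patches)), 0)
})

test_that("augmentation is reproducible under a fixed seed", {
  set.seed(34)
  src <- PatchSet(array(runif(12 * 12 * 2), c(12, 12, 2)), matrix(1L, 2, 2))
  gnd <- PatchSet(array(rbinom(12 * 12 * 2, 1, 0.2), c(12, 12, 2)),
                  matrix(1L, 2, 2))
  set.seed(35)
  a <- augmentPatchSet(src, gnd)
  set.seed(35)
  b <- augmentPatchSet(src, gnd)
  expect_identical(a$source@patches, b$source@patches)
  expect_identical(a$ground@patches, b$ground@patches)
})

test_that("warps approximately preserve vessel mass at default strength", {
  # statistical sanity band over many seeds: vessel fraction of the warped
  # label stays within +/-30% of the original
  set.seed(36)
  gt <- matrix(0, 48, 48)
  gt[20:28, ] <- 1 # a thick band, fraction ~0.19
  img <- matrix(runif(48 * 48), 48, 48)
  fracs <- replicate(100, {
    f <- randomDisplacementField(c(48, 48), 4, 8)
    mean(applyDeformation(img, gt, f)$gt)
  })
  f0 <- mean(gt)
  expect_true(all(fracs > 0.7 * f0 & fracs < 1.3 * f0))
})
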