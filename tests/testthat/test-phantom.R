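test_that("phantoms satisfy the triplet contract", {
  tr <- generatePhantom(PhantomSpec(), seed = 71)
  expect_s4_class(tr, "ImageTriplet")
  expect_identical(dim(sourceImage(tr)), c(128L, 128L, 3L))
  expect_true(all(groundTruth(tr) %in% c(0, 1)))
  expect_true(all(fovMask(tr) %in% c(0, 1)))

  # FOV is the centered disc defined by the radius predicate
  fov <- fovMask(tr)
  R <- 0.92 * 64
  d2 <- outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, "+")
  expect_identical(fov, matrix(as.numeric(d2 <= R^2), 128, 128))

  # vessels never leave the FOV
  expect_true(all(groundTruth(tr)[fov == 0] == 0))
})

test_that("phantom generation is bit-reproducible under a seed", {
  a <- generatePhantom(PhantomSpec(), seed = 72)
  b <- generatePhantom(PhantomSpec(), seed = 72)
  expect_identical(sourceImage(a), sourceImage(b))
  expect_identical(groundTruth(a), groundTruth(b))
})

test_that("vessel fraction stays in the 5-20% prevalence band", {
  fracs <- sapply(1:20, function(s) {
    tr <- generatePhantom(PhantomSpec(), seed = 100 + s)
    mean(groundTruth(tr)[fovMask(tr) == 1])
  })
  expect_true(all(fracs >= 0.05 & fracs <= 0.20))
})

test_that("vessel widths fall in the configured 1-4 px range", {
  # morphological probe: max erosion depth bounds the half-width
  tr <- generatePhantom(PhantomSpec(), seed = 73)
  gt <- groundTruth(tr)
  kern <- matrix(1, 3, 3)
  er <- EBImage::erode(EBImage::Image(t(gt)), kern)
  er2 <- EBImage::erode(er, kern)
  # widths <= 4 px: two erosions by a 3x3 kernel leave nothing
  expect_equal(sum(EBImage::imageData(er2)), 0)
  expect_gt(sum(gt), 0)
})

test_that("datasets are independent and reproducible from the master seed", {
  expect_identical(generatePhantomDataset(0), list())
  a <- generatePhantomDataset(5, PhantomSpec(height = 64, width = 64),
                              seed = 74)
  expect_length(a, 5)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(groundTruth(a[[i]]), groundTruth(a[[j]])))
  b <- generatePhantomDataset(5, PhantomSpec(height = 64, width = 64),
                              seed = 74)
  for (i in 1:5)
    expect_identical(sourceImage(a[[i]]), sourceImage(b[[i]]))
})

test_that("phantom spec validity is enforced", {
  expect_error(PhantomSpec(widthRange = c(1, 6)), "widthRange")
  expect_error(PhantomSpec(fovRadiusFrac = 1.5), "fovRadiusFrac")
  expect_error(PhantomSpec(height = 16), "32")
})
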