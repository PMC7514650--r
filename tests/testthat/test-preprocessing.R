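test_that("grayscale conversion is the expected weighted channel mix", {
  z <- array(0, c(4, 4, 3))
  expect_equal(toGrayscale(z), matrix(0, 4, 4))

  const <- array(7, c(5, 3, 3))
  expect_equal(toGrayscale(const), matrix(7, 5, 3)) # weights sum to 1

  set.seed(10)
  img <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  wts <- c(0.299, 0.587, 0.114)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- sum(img[i, j, ] * wts)
  expect_equal(toGrayscale(img), oracle, tolerance = 1e-12)

  expect_equal(toGrayscale(img, mode = "green"), img[, , 2])
  expect_equal(toGrayscale(oracle), oracle) # single channel passes through
  expect_error(toGrayscale(array(1, c(3, 3, 2))), "channels")
})

test_that("dataset statistics are pooled moments over all pixels", {
  expect_error(computeDatasetStats(list(matrix(5, 1, 1))), "zero variance")

  s <- computeDatasetStats(list(matrix(c(0, 0), 1), matrix(c(2, 2), 1)))
  expect_equal(s@mu, 1)
  expect_equal(s@sigma, 1) # population form

  set.seed(11)
  imgs <- lapply(1:10, function(i)
    matrix(runif(12 * 15, 0, 255), 12, 15))
  pooled <- unlist(imgs)
  s <- computeDatasetStats(imgs)
  expect_equal(s@mu, mean(pooled), tolerance = 1e-12)
  expect_equal(s@sigma, sqrt(mean((pooled - mean(pooled))^2)),
               tolerance = 1e-12)
})

test_that("normalization centers and scales; self-normalized set is N(0,1)", {
  st <- NormalizationStats(50, 10)
  expect_equal(normalizeImage(matrix(50, 3, 3), st), matrix(0, 3, 3))
  expect_equal(normalizeImage(matrix(60, 1, 1), st), matrix(1, 1, 1))

  set.seed(12)
  imgs <- lapply(1:6, function(i) matrix(runif(20 * 20, 0, 255), 20, 20))
  st <- computeDatasetStats(imgs)
  normed <- unlist(lapply(imgs, normalizeImage, stats = st))
  expect_lt(abs(mean(normed)), 1e-6)
  expect_lt(abs(sqrt(mean((normed - mean(normed))^2)) - 1), 1e-6)
})

test_that("normalization is affine-equivariant", {
  set.seed(13)
  x <- matrix(runif(10 * 10, 0, 255), 10, 10)
  st <- NormalizationStats(100, 25)
  a <- 2; b <- 5
  lhs <- normalizeImage(a * x + b, st)
  rhs <- (a * x + b - st@mu) / st@sigma
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("degenerate stats are rejected", {
  expect_error(NormalizationStats(0, 0), "sigma")
  expect_error(computeDatasetStats(list()), "at least one")
})
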