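# brute-force visit counting oracle
visitCounts <- function(imgH, imgW, geom) {
  cnt <- countOverlapPatches(imgH, imgW, geom)
  v <- matrix(0, imgH, imgW)
  for (a in seq_len(cnt$nH)) for (b in seq_len(cnt$nW)) {
    top <- (a - 1) * geom@strideH + 1
    left <- (b - 1) * geom@strideW + 1
    sel <- cbind(rep(top:(top + geom@patchH - 1), geom@patchW),
                 rep(left:(left + geom@patchW - 1), each = geom@patchH))
    v[sel] <- v[sel] + 1
  }
  v
}

test_that("accumulation counts visits and sums probabilities", {
  geom <- PatchGeometry(2, 2, 1, 1)
  acc <- accumulatePatches(array(1, c(2, 2, 9)), geom, 4, 4)
  expect_equal(acc@fullSum, visitCounts(4, 4, geom))
  expect_equal(acc@fullSum[2, 2], 4)
  expect_equal(acc@fullSum[1, 1], 1)
  expect_equal(acc@fullPro, acc@fullSum) # all-ones predictions

  one <- accumulatePatches(array(0.3, c(6, 6, 1)), PatchGeometry(6, 6, 6, 6),
                           6, 6)
  expect_true(all(one@fullSum == 1))
  expect_equal(one@fullPro, matrix(0.3, 6, 6))

  zero <- accumulatePatches(array(0, c(2, 2, 9)), geom, 4, 4)
  expect_true(all(zero@fullPro == 0))
  expect_true(all(zero@fullSum > 0))
})

test_that("accumulation rejects bad inputs", {
  geom <- PatchGeometry(2, 2, 1, 1)
  expect_error(accumulatePatches(array(1, c(2, 2, 5)), geom, 4, 4),
               "tiling mismatch")
  expect_error(accumulatePatches(array(2, c(2, 2, 9)), geom, 4, 4),
               "probability")
})

test_that("finalize divides by visits and flags uncovered pixels", {
  acc <- new("AccumulatorPair", fullPro = matrix(1, 3, 3),
             fullSum = matrix(2, 3, 3))
  pm <- finalizeAccumulator(acc)
  expect_equal(mapValues(pm), matrix(0.5, 3, 3))

  # uncovered margin: 5x5 image, 3x3 patch, stride 2 covers all; use
  # stride that leaves a remainder
  geom <- PatchGeometry(3, 3, 3, 3)
  pm <- reconstructMap(array(1, c(3, 3, 1)), geom, 5, 5)
  expect_false(any(mapCoverage(pm)[4:5, ]))
  expect_true(all(mapValues(pm)[4:5, ] == 0))
})

test_that("reconstruction identity: cropped map reassembles exactly", {
  set.seed(20)
  for (i in 1:10) {
    ph <- sample(3:8, 1)
    geom <- PatchGeometry(ph, ph, sample(ph, 1), sample(ph, 1))
    ih <- ph + sample(0:12, 1); iw <- ph + sample(0:12, 1)
    P <- matrix(runif(ih * iw), ih, iw)
    tiles <- extractOverlapPatches(P, geom)
    pm <- reconstructMap(tiles@patches, geom, ih, iw)
    cov <- mapCoverage(pm)
    expect_lt(max(abs(mapValues(pm)[cov] - P[cov])), 1e-6)
    expect_equal(cov, visitCounts(ih, iw, geom) > 0)
  }
})

test_that("constant predictions reconstruct the constant; range respected", {
  geom <- PatchGeometry(4, 4, 3, 3)
  n <- countOverlapPatches(10, 13, geom)$nTotal
  pm <- reconstructMap(array(0.42, c(4, 4, n)), geom, 10, 13)
  expect_true(all(abs(mapValues(pm)[mapCoverage(pm)] - 0.42) < 1e-12))
  expect_gte(min(mapValues(pm)), 0)
  expect_lte(max(mapValues(pm)), 1)
})

test_that("raster order matters unless all patches are equal", {
  set.seed(21)
  geom <- PatchGeometry(3, 3, 2, 2)
  P <- matrix(runif(7 * 7), 7, 7)
  tiles <- extractOverlapPatches(P, geom)@patches
  shuffled <- tiles[, , rev(seq_len(dim(tiles)[3]))]
  a <- mapValues(reconstructMap(tiles, geom, 7, 7))
  b <- mapValues(reconstructMap(shuffled, geom, 7, 7))
  expect_gt(max(abs(a - b)), 1e-6)
})

test_that("probability maps round-trip losslessly through the float dump", {
  set.seed(22)
  geom <- PatchGeometry(4, 4, 2, 2)
  n <- countOverlapPatches(9, 9, geom)$nTotal
  pm <- reconstructMap(array(runif(4 * 4 * n), c(4, 4, n)), geom, 9, 9)
  f <- tempfile(fileext = ".bin")
  writeProbabilityMap(pm, binPath = f)
  back <- readProbabilityMap(f)
  expect_identical(mapValues(back), mapValues(pm))
  expect_identical(mapCoverage(back), mapCoverage(pm))
  unlink(f)
})
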