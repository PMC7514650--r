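test_that("binarization uses the >= convention", {
  expect_equal(binarizeMap(matrix(0.6, 2, 2), 0.5), matrix(1, 2, 2))
  expect_equal(binarizeMap(matrix(0.5, 1, 1), 0.5), matrix(1, 1, 1))
  expect_equal(binarizeMap(matrix(c(0, 0.2), 1), 0), matrix(c(1, 1), 1))
})

test_that("confusion counts restrict to the mask and match hand counts", {
  gt <- matrix(c(1, 1, 0, 0), 2)
  pred <- matrix(c(1, 0, 1, 0), 2)
  cc <- confusionCounts(pred, gt, matrix(1, 2, 2))
  expect_equal(c(cc@tp, cc@fn, cc@fp, cc@tn), c(1, 1, 1, 1))

  cc2 <- confusionCounts(gt, gt, matrix(1, 2, 2))
  expect_equal(c(cc2@fn, cc2@fp), c(0, 0))

  mask0 <- matrix(0, 2, 2)
  cc3 <- confusionCounts(pred, gt, mask0)
  expect_equal(cc3@tp + cc3@fn + cc3@tn + cc3@fp, 0)
  w <- capture_warnings(m <- seSpAcc(cc3))
  expect_length(w, 3) # each metric flagged undefined
  expect_true(all(is.na(m)))

  expect_error(confusionCounts(matrix(0.5, 2, 2), gt), "binary")
})

test_that("Se/Sp/Acc follow their defining ratios", {
  cc <- new("ConfusionCounts", tp = 1, fn = 1, tn = 1, fp = 1)
  expect_equal(unname(seSpAcc(cc)), c(0.5, 0.5, 0.5))
  perfect <- new("ConfusionCounts", tp = 10, fn = 0, tn = 30, fp = 0)
  expect_equal(unname(seSpAcc(perfect)), c(1, 1, 1))
  noPos <- new("ConfusionCounts", tp = 0, fn = 0, tn = 5, fp = 2)
  expect_warning(m <- seSpAcc(noPos), "sensitivity")
  expect_true(is.na(m[["se"]]))
})

test_that("Se/Sp/Acc agree with a per-pixel counting loop on random grids", {
  set.seed(50)
  for (i in 1:20) {
    h <- sample(5:15, 1); w <- sample(5:15, 1)
    gt <- matrix(rbinom(h * w, 1, 0.4), h, w)
    pred <- matrix(rbinom(h * w, 1, 0.5), h, w)
    mask <- matrix(rbinom(h * w, 1, 0.7), h, w)
    tp <- fn <- tn <- fp <- 0
    for (r in 1:h) for (c in 1:w) if (mask[r, c] == 1) {
      if (gt[r, c] == 1 && pred[r, c] == 1) tp <- tp + 1
      if (gt[r, c] == 1 && pred[r, c] == 0) fn <- fn + 1
      if (gt[r, c] == 0 && pred[r, c] == 0) tn <- tn + 1
      if (gt[r, c] == 0 && pred[r, c] == 1) fp <- fp + 1
    }
    cc <- confusionCounts(pred, gt, mask)
    expect_equal(c(cc@tp, cc@fn, cc@tn, cc@fp), c(tp, fn, tn, fp))
    if (tp + fn > 0 && tn + fp > 0) {
      m <- seSpAcc(cc)
      expect_equal(m[["se"]], tp / (tp + fn))
      expect_equal(m[["sp"]], tn / (tn + fp))
      expect_equal(m[["acc"]], (tp + tn) / (tp + fn + tn + fp))
      # Acc = prevalence * Se + (1 - prevalence) * Sp
      prev <- (tp + fn) / (tp + fn + tn + fp)
      expect_equal(m[["acc"]], prev * m[["se"]] + (1 - prev) * m[["sp"]],
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC equals the pairwise Mann-Whitney count with ties", {
  set.seed(51)
  for (i in 1:10) {
    n <- 200
    # quantized scores force ties
    p <- matrix(round(runif(n), 2), 10, 20)
    g <- matrix(rbinom(n, 1, 0.3), 10, 20)
    if (sum(g) == 0 || sum(g) == n) next
    expect_equal(aucScore(p, g), aucPairwise(as.vector(p), as.vector(g)),
                 tolerance = 1e-12)
  }
})

test_that("AUC handles degenerate and canonical cases", {
  g <- matrix(c(1, 1, 0, 0), 2)
  sep <- matrix(c(0.9, 0.8, 0.1, 0.2), 2)
  expect_equal(aucScore(sep, g), 1)
  expect_equal(aucScore(matrix(0.5, 2, 2), g), 0.5)
  expect_warning(a <- aucScore(sep, matrix(1, 2, 2)), "one class")
  expect_true(is.na(a))
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(52)
  p <- matrix(runif(100), 10, 10)
  g <- matrix(rbinom(100, 1, 0.4), 10, 10)
  a <- aucScore(p, g)
  expect_equal(aucScore(p^3, g), a)
  expect_equal(aucScore(matrix(plogis(5 * p), 10, 10), g), a)
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  p <- matrix(runif(400), 20, 20)
  g <- matrix(rbinom(400, 1, 0.25), 20, 20)
  ref <- suppressMessages(
    as.numeric(pROC::auc(as.vector(g), as.vector(p), direction = "<")))
  expect_equal(aucScore(p, g), ref, tolerance = 1e-12)
})

test_that("evaluateMap bundles consistent metrics", {
  set.seed(54)
  gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  rep <- evaluateMap(gt, gt, threshold = 0.5)
  expect_equal(c(rep@se, rep@sp, rep@acc, rep@auc), c(1, 1, 1, 1))
  m <- seSpAcc(rep@counts)
  expect_equal(c(rep@se, rep@sp, rep@acc), unname(m))
})

test_that("Otsu threshold separates a bimodal probability map", {
  set.seed(55)
  low <- runif(200, 0, 0.1)
  high <- runif(200, 0.9, 1)
  t <- otsuThreshold(matrix(c(low, high), 20, 20))
  expect_true(all(low < t))
  expect_true(all(high >= t))
})
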