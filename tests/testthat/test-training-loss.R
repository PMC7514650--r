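test_that("dice coefficient matches hand evaluations", {
  g <- c(1, 0, 1, 1, 0)
  expect_equal(diceCoefficient(g, g), 1, tolerance = 1e-6)
  expect_equal(diceCoefficient(c(1, 1, 0), c(0, 0, 1)), 0, tolerance = 1e-6)
  expect_equal(diceCoefficient(c(0.5, 0.5), c(1, 0)), 2 / 3,
               tolerance = 1e-5)
  # all-background case defined as 1 by smoothing
  expect_equal(diceCoefficient(rep(0, 10), rep(0, 10)), 1)
  expect_error(diceCoefficient(1:3 / 3, c(0, 1)), "equal length")
})

test_that("dice is bounded and symmetric on binary inputs", {
  set.seed(40)
  for (i in 1:50) {
    p <- runif(30)
    g <- rbinom(30, 1, 0.4)
    d <- diceCoefficient(p, g)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  pb <- rbinom(40, 1, 0.5)
  gb <- rbinom(40, 1, 0.5)
  expect_equal(diceCoefficient(pb, gb), diceCoefficient(gb, pb))
})

test_that("dice gradient is non-positive for empty ground truth", {
  # with g identically 0 the overlap term vanishes, so the gradient is
  # -2 p_j eps / den^2: non-positive and vanishing with the smoothing
  set.seed(41)
  p <- runif(20, 0.1, 0.9)
  gr <- diceGradient(p, rep(0, 20))
  expect_true(all(gr <= 0))
  expect_equal(gr, -2 * p * 1e-6 / (sum(p^2) + 1e-6)^2, tolerance = 1e-12)
})

test_that("analytic gradient equals central finite differences", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 50
    p <- runif(n, 0.05, 0.95)
    g <- rbinom(n, 1, 0.3)
    an <- diceGradient(p, g)
    eps <- 1e-6
    for (j in sample(n, 5)) {
      pp <- p; pp[j] <- p[j] + eps
      pm <- p; pm[j] <- p[j] - eps
      fd <- (diceCoefficient(pp, g) - diceCoefficient(pm, g)) / (2 * eps)
      expect_lt(abs(fd - an[j]) / max(abs(fd), 1e-10), 1e-4)
    }
  }
})

test_that("dice loss is 1 - coefficient with negated gradient", {
  set.seed(43)
  p <- runif(25); g <- rbinom(25, 1, 0.5)
  expect_equal(diceLoss(p, g), 1 - diceCoefficient(p, g))
  expect_equal(diceLoss(g, g), 0, tolerance = 1e-6)
  expect_equal(diceLoss(c(1, 0), c(0, 1)), 1, tolerance = 1e-5)
})

test_that("a short optimization run strictly decreases the training loss", {
  set.seed(44)
  net <- buildDenseUnet(tinyDenseConfig())
  n <- 8
  src <- array(rnorm(16 * 16 * n), c(16, 16, n))
  gnd <- array(0, c(16, 16, n))
  gnd[6:10, , ] <- 1
  fit <- trainNetwork(net, src, gnd,
                      TrainConfig(epochs = 20, batchSize = 8,
                                  validationFraction = 0.125, seed = 44))
  expect_lt(tail(fit$report@trainLoss, 1), fit$report@trainLoss[1])
  expect_identical(length(fit$report@valDice), 20L)
})

test_that("training is bit-reproducible on CPU under a fixed seed", {
  cfg <- tinyDenseConfig(dropout = 0.2)
  set.seed(45)
  src <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  gnd <- array(rbinom(16 * 16 * 10, 1, 0.2), c(16, 16, 10))
  run <- function() {
    set.seed(46)
    net <- buildDenseUnet(cfg)
    trainNetwork(net, src, gnd,
                 TrainConfig(epochs = 3, batchSize = 4, seed = 9))
  }
  a <- run(); b <- run()
  expect_identical(a$report@trainLoss, b$report@trainLoss)
  expect_identical(a$report@valDice, b$report@valDice)
  expect_identical(a$net@params, b$net@params)
})

test_that("cross-entropy loss also descends and aborts on bad inputs", {
  set.seed(47)
  net <- buildDenseUnet(tinyDenseConfig())
  src <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  gnd <- array(rbinom(16 * 16 * 6, 1, 0.3), c(16, 16, 6))
  fit <- trainNetwork(net, src, gnd,
                      TrainConfig(epochs = 10, batchSize = 6,
                                  validationFraction = 0.2, seed = 47,
                                  lossKind = "cross_entropy"))
  expect_lt(tail(fit$report@trainLoss, 1), fit$report@trainLoss[1])
  expect_error(trainNetwork(net, src[, , 1, drop = FALSE],
                            gnd[, , 1, drop = FALSE],
                            TrainConfig(epochs = 1, seed = 1)),
               "too-small")
  expect_error(trainNetwork(net, src, gnd[, , 1:3],
                            TrainConfig(epochs = 1, seed = 1)), "aligned")
})
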