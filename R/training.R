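#' @include network.R
NULL

.DICE_EPS <- 1e-6

#' Dice coefficient between prediction and ground truth
#'
#' `D = 2 * sum(p * g) / (sum(p^2) + sum(g^2))`, computed jointly over all
#' supplied pixels, with a small smoothing constant added to numerator and
#' denominator so the all-background case (`p` and `g` identically zero) is
#' defined as 1.
#'
#' @param p predicted values in `[0, 1]`.
#' @param g ground truth in `{0, 1}`.
#' @param eps smoothing constant.
#' @return scalar in `[0, 1]`.
#' @examples
#' diceCoefficient(c(0.5, 0.5), c(1, 0)) # 2/3 up to smoothing
#' @export
diceCoefficient <- function(p, g, eps = .DICE_EPS) {
  if (length(p) != length(g)) stop("p and g must have equal length")
  (2 * sum(p * g) + eps) / (sum(p * p) + sum(g * g) + eps)
}

#' Analytic gradient of the dice coefficient
#'
#' `dD/dp_j = 2 * [g_j * (sum p^2 + sum g^2) - 2 * p_j * sum(p g)] /
#' (sum p^2 + sum g^2)^2`, with the same smoothing constant as
#' [diceCoefficient()] folded into both sums.
#'
#' @inheritParams diceCoefficient
#' @return gradient vector, same length as `p`.
#' @export
diceGradient <- function(p, g, eps = .DICE_EPS) {
  if (length(p) != length(g)) stop("p and g must have equal length")
  den <- sum(p * p) + sum(g * g) + eps
  num <- 2 * sum(p * g) + eps
  (2 * g * den - 2 * p * num) / den^2
}

#' Dice loss
#'
#' `L = 1 - D`; its gradient is the negated [diceGradient()].
#'
#' @inheritParams diceCoefficient
#' @return scalar loss in `[0, 1]`.
#' @export
diceLoss <- function(p, g, eps = .DICE_EPS) 1 - diceCoefficient(p, g, eps)

# loss value and dL/dp for a batch (vectors)
.lossAndGrad <- function(p, g, kind) {
  if (kind == "dice") {
    list(loss = diceLoss(p, g), dp = -diceGradient(p, g))
  } else {
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    n <- length(p)
    list(loss = -sum(g * log(pc) + (1 - g) * log(1 - pc)) / n,
         dp = (pc - g) / (pc * (1 - pc)) / n)
  }
}

# recursive SGD-with-momentum step over nested parameter lists; gradient
# lists are matched by name where names exist (construction order differs)
.sgdStep <- function(p, g, v, lr, mom) {
  if (is.list(p)) {
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (i in keys) {
      r <- .sgdStep(p[[i]], g[[i]], v[[i]], lr, mom)
      p[[i]] <- r$p; v[[i]] <- r$v
    }
    list(p = p, v = v)
  } else {
    v <- mom * v - lr * g
    list(p = p + v, v = v)
  }
}

.zeroLike <- function(p) rapply(p, function(x) x * 0, how = "replace")

#' Train a segmentation network with SGD and momentum
#'
#' Holds out a validation fraction of the patch pairs (seeded split), then
#' runs mini-batch SGD with momentum for the configured number of epochs,
#' recording training loss, validation loss and validation dice per epoch.
#' The weights with the best validation dice are retained in the returned
#' model. All randomness (split, shuffling, dropout) flows from
#' `config@seed`, so runs are bit-reproducible on CPU.
#'
#' @param net a freshly built [VesselNet-class].
#' @param source array (h x w x n) of normalized intensity patches or a
#'   [PatchSet-class].
#' @param ground aligned binary label patches.
#' @param config a [TrainConfig-class].
#' @param verbose print one line per epoch.
#' @return list with `net` (trained model, best-validation weights) and
#'   `report` (a [LossReport-class]).
#' @export
trainNetwork <- function(net, source, ground, config, verbose = FALSE) {
  stopifnot(is(net, "VesselNet"), is(config, "TrainConfig"))
  if (is(source, "PatchSet")) source <- source@patches
  if (is(ground, "PatchSet")) ground <- ground@patches
  if (!identical(dim(source), dim(ground)))
    stop("source and ground patch arrays must be aligned")
  n <- dim(source)[3]
  if (n < 2) stop("empty or too-small training set")
  h <- dim(source)[1]; w <- dim(source)[2]

  set.seed(config@seed)
  nVal <- max(1L, round(config@validationFraction * n))
  valIdx <- sample.int(n, nVal)
  trIdx <- setdiff(seq_len(n), valIdx)
  if (!length(trIdx)) stop("no training patches left after validation split")

  vel <- .zeroLike(net@params)
  trainLoss <- valLoss <- valDice <- numeric(config@epochs)
  best <- list(dice = -Inf, params = net@params, state = net@state,
               epoch = 0L)

  for (epoch in seq_len(config@epochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    eLoss <- 0
    for (bt in batches) {
      x <- array(source[, , bt], c(h, w, 1L, length(bt)))
      g <- as.vector(ground[, , bt])
      fw <- .netForward(net, x, training = TRUE)
      net@state <- fw$state
      p <- as.vector(fw$prob)
      lg <- .lossAndGrad(p, g, config@lossKind)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; try a smaller learning rate")
      eLoss <- eLoss + lg$loss * length(bt)
      dz <- array(lg$dp * p * (1 - p), dim(fw$prob)) # through sigmoid
      grads <- .netBackward(net, fw$cache, dz)
      r <- .sgdStep(net@params, grads, vel, config@learningRate,
                    config@momentum)
      net@params <- r$p
      vel <- r$v
    }
    trainLoss[epoch] <- eLoss / length(ord)

    vp <- as.vector(predictPatches(net, source[, , valIdx, drop = FALSE],
                                   config@batchSize))
    vg <- as.vector(ground[, , valIdx, drop = FALSE])
    vl <- .lossAndGrad(vp, vg, config@lossKind)$loss
    vd <- diceCoefficient(vp, vg)
    valLoss[epoch] <- vl
    valDice[epoch] <- vd
    if (vd > best$dice)
      best <- list(dice = vd, params = net@params, state = net@state,
                   epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val dice %.4f",
                      epoch, trainLoss[epoch], vl, vd))
  }
  net@params <- best$params
  net@state <- best$state
  report <- new("LossReport", trainLoss = trainLoss, valLoss = valLoss,
                valDice = valDice, bestEpoch = as.integer(best$epoch),
                seed = config@seed)
  list(net = net, report = report)
}
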