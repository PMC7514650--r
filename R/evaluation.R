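#' @include AllClasses.R
NULL

#' Binarize a probability map
#'
#' @param prob a [ProbabilityMap-class] or numeric matrix.
#' @param threshold pixels with `p >= threshold` become 1.
#' @return binary matrix.
#' @examples
#' binarizeMap(matrix(c(0.2, 0.8), 1), 0.5)
#' @export
binarizeMap <- function(prob, threshold = 0.5) {
  v <- if (is(prob, "ProbabilityMap")) prob@values else prob
  matrix(as.numeric(v >= threshold), nrow(v), ncol(v))
}

#' Otsu threshold of a probability map
#'
#' Alternative automatic binarization rule: maximizes between-class
#' variance of the masked probabilities on a 256-bin histogram.
#'
#' @param prob a [ProbabilityMap-class] or matrix.
#' @param mask optional binary matrix restricting the histogram.
#' @return scalar threshold in `[0, 1]`.
#' @export
otsuThreshold <- function(prob, mask = NULL) {
  v <- if (is(prob, "ProbabilityMap")) prob@values else prob
  if (!is.null(mask)) v <- v[mask == 1]
  h <- tabulate(pmin(floor(as.vector(v) * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5) / 256)
  muT <- mu[256]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  (which.max(sigmaB)) / 256
}

#' Pixel confusion counts inside a mask
#'
#' Counts TP/FN/TN/FP over the pixels where `mask == 1` only (by default
#' the FOV, the standard convention for fundus benchmarks).
#'
#' @param predBinary binary matrix of predicted labels.
#' @param gt binary ground-truth matrix.
#' @param mask binary evaluation mask.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusionCounts(matrix(c(1, 0, 1, 0), 2), matrix(c(1, 1, 0, 0), 2),
#'                 matrix(1, 2, 2))
#' @export
confusionCounts <- function(predBinary, gt, mask = NULL) {
  if (!identical(dim(predBinary), dim(gt)))
    stop("prediction and ground truth sizes differ")
  if (!.isBinary(predBinary) || !.isBinary(gt))
    stop("prediction and ground truth must be binary (0/1)")
  if (is.null(mask)) mask <- matrix(1, nrow(gt), ncol(gt))
  sel <- mask == 1
  p <- predBinary[sel]; g <- gt[sel]
  new("ConfusionCounts",
      tp = sum(p == 1 & g == 1), fn = sum(p == 0 & g == 1),
      tn = sum(p == 0 & g == 0), fp = sum(p == 1 & g == 0))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc = (TP+TN)/(TP+FN+TN+FP)`. A zero denominator yields `NA` with a
#' warning.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric vector `c(se, sp, acc)`.
#' @export
seSpAcc <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fn <- counts@fn; tn <- counts@tn; fp <- counts@fp
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: empty denominator"); NA_real_ }
    else num / den
  }
  c(se = ratio(tp, tp + fn, "sensitivity"),
    sp = ratio(tn, tn + fp, "specificity"),
    acc = ratio(tp + tn, tp + fn + tn + fp, "accuracy"))
}

#' Area under the ROC curve of masked pixel probabilities
#'
#' Exact tie-aware AUC via the rank (Mann-Whitney) formulation: equal to
#' the probability that a random vessel pixel scores above a random
#' background pixel, ties counted half — identical to the trapezoidal area
#' under the ROC curve over all distinct thresholds.
#'
#' @param prob a [ProbabilityMap-class] or numeric matrix of scores.
#' @param gt binary ground-truth matrix.
#' @param mask binary evaluation mask (NULL for all pixels).
#' @return scalar AUC, or `NA` with a warning if only one class is present.
#' @export
aucScore <- function(prob, gt, mask = NULL) {
  v <- if (is(prob, "ProbabilityMap")) prob@values else prob
  if (!identical(dim(v), dim(gt))) stop("sizes differ")
  if (is.null(mask)) mask <- matrix(1, nrow(gt), ncol(gt))
  sel <- mask == 1
  p <- as.vector(v[sel]); g <- as.vector(gt[sel])
  nPos <- sum(g == 1); nNeg <- sum(g == 0)
  if (nPos == 0 || nNeg == 0) {
    warning("AUC undefined: only one class inside the mask")
    return(NA_real_)
  }
  r <- rank(p) # average ranks handle ties as half-counts
  (sum(r[g == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate a probability map against ground truth
#'
#' Binarizes at the threshold, computes FOV-masked confusion counts,
#' Se/Sp/Acc and AUC, and bundles them into a report.
#'
#' @param prob a [ProbabilityMap-class] or matrix.
#' @param gt binary ground truth.
#' @param mask binary evaluation mask (typically the FOV); NULL evaluates
#'   every pixel.
#' @param threshold binarization threshold.
#' @return A [MetricReport-class].
#' @export
evaluateMap <- function(prob, gt, mask = NULL, threshold = 0.5) {
  v <- if (is(prob, "ProbabilityMap")) prob@values else prob
  if (is.null(mask)) mask <- matrix(1, nrow(gt), ncol(gt))
  counts <- confusionCounts(binarizeMap(v, threshold), gt, mask)
  m <- seSpAcc(counts)
  auc <- if (sum(mask == 1) == 0) NA_real_ else
    suppressWarnings(aucScore(v, gt, mask))
  new("MetricReport", se = m[["se"]], sp = m[["sp"]], acc = m[["acc"]],
      auc = auc, threshold = threshold, nPixels = sum(mask == 1),
      counts = counts)
}
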