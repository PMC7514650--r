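#' @include AllClasses.R
NULL

#' Number of trainable parameters
#'
#' Sums the sizes of every trainable tensor (convolution weights and biases,
#' batch-norm scales and shifts) of a built network.
#'
#' @param object a [VesselNet-class].
#' @return integer parameter count.
#' @export
setGeneric("countParameters",
           function(object) standardGeneric("countParameters"))

#' Analytic model descriptor
#'
#' Returns the ModelSpec recorded when the network was built: an ordered
#' layer table (kind, spatial size, input/output channels, parameters) plus
#' the per-dense-block channel traces.
#'
#' @param object a [VesselNet-class].
#' @return a list with elements `layers` (data.frame) and `blocks`.
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))

#' Accessors for ImageTriplet
#'
#' @param object an [ImageTriplet-class].
#' @return the corresponding slot.
#' @name triplet-accessors
NULL

#' @rdname triplet-accessors
#' @export
setGeneric("sourceImage", function(object) standardGeneric("sourceImage"))
#' @rdname triplet-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname triplet-accessors
#' @export
setGeneric("fovMask", function(object) standardGeneric("fovMask"))
#' @rdname triplet-accessors
#' @export
setGeneric("tripletId", function(object) standardGeneric("tripletId"))

setMethod("sourceImage", "ImageTriplet", function(object) object@image)
setMethod("groundTruth", "ImageTriplet", function(object) object@groundTruth)
setMethod("fovMask", "ImageTriplet", function(object) object@fov)
setMethod("tripletId", "ImageTriplet", function(object) object@id)

#' Probability-map accessors
#'
#' @param object a [ProbabilityMap-class].
#' @return matrix of probabilities / logical coverage matrix.
#' @name probmap-accessors
NULL

#' @rdname probmap-accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname probmap-accessors
#' @export
setGeneric("mapCoverage", function(object) standardGeneric("mapCoverage"))

setMethod("mapValues", "ProbabilityMap", function(object) object@values)
setMethod("mapCoverage", "ProbabilityMap", function(object) object@coverage)

setMethod("show", "ImageTriplet", function(object) {
  d <- dim(object@image)
  cat(sprintf("ImageTriplet '%s': %d x %d (%s), vessel fraction %.3f\n",
              object@id, d[1], d[2],
              if (length(d) == 3) "color" else "gray",
              mean(object@groundTruth[object@fov == 1])))
})

setMethod("show", "PatchGeometry", function(object) {
  cat(sprintf("PatchGeometry: patch %d x %d, stride %d x %d\n",
              object@patchH, object@patchW, object@strideH, object@strideW))
})

setMethod("show", "PatchSet", function(object) {
  d <- dim(object@patches)
  cat(sprintf("PatchSet (%s): %d patches of %d x %d from '%s'\n",
              object@ordering, d[3], d[1], d[2], object@sourceId))
})

setMethod("show", "NormalizationStats", function(object) {
  cat(sprintf("NormalizationStats: mu = %.4f, sigma = %.4f\n",
              object@mu, object@sigma))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: growth %d, stem %d, %d dense blocks x %d layers, patch %d, dropout %.2f, upsample %s\n",
    object@growthRate, object@initChannels, object@nDenseBlocks,
    object@layersPerBlock, object@patchSize, object@dropout,
    object@upsampleMode))
})

setMethod("show", "VesselNet", function(object) {
  cat(sprintf("VesselNet (%s): %s trainable parameters\n", object@arch,
              format(countParameters(object), big.mark = ",")))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap %d x %d: %.1f%% covered, mean p = %.3f\n",
              nrow(object@values), ncol(object@values),
              100 * mean(object@coverage),
              mean(object@values[object@coverage])))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(
    "MetricReport (threshold %.2f, %d px): Se %.4f  Sp %.4f  Acc %.4f  AUC %.4f\n",
    object@threshold, object@nPixels, object@se, object@sp, object@acc,
    object@auc))
})

setMethod("show", "LossReport", function(object) {
  n <- length(object@trainLoss)
  cat(sprintf(
    "LossReport: %d epochs, final train loss %.4f, best val dice %.4f (epoch %d)\n",
    n, object@trainLoss[n], max(object@valDice), object@bestEpoch))
})
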