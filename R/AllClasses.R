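#' @include DenseVessel-package.R
NULL

.isBinary <- function(m) all(m %in% c(0, 1))

#' ImageTriplet: fundus image, vessel ground truth and FOV mask
#'
#' The unit of all dataset I/O: a source image (grayscale matrix or
#' height x width x 3 color array), a binary vessel ground-truth map and a
#' binary field-of-view (FOV) mask of identical height and width.
#'
#' @slot image numeric matrix (H x W) or array (H x W x 3), intensities in
#'   `[0, 255]`.
#' @slot groundTruth binary matrix (values 0/1), expert vessel map.
#' @slot fov binary matrix (values 0/1), 1 inside the circular field of view.
#' @slot id character label (file stem or phantom id).
#' @export
setClass("ImageTriplet",
  representation(image = "array", groundTruth = "matrix",
                 fov = "matrix", id = "character"),
  validity = function(object) {
    d <- dim(object@image)
    if (!(length(d) %in% c(2L, 3L)))
      return("image must be 2-d (grayscale) or 3-d (H x W x channels)")
    if (length(d) == 3L && d[3] != 3L)
      return("3-d image must have exactly 3 channels")
    if (!identical(d[1:2], dim(object@groundTruth)))
      return("ground truth size differs from image")
    if (!identical(d[1:2], dim(object@fov)))
      return("FOV mask size differs from image")
    if (!.isBinary(object@groundTruth)) return("ground truth must be 0/1")
    if (!.isBinary(object@fov)) return("FOV mask must be 0/1")
    TRUE
  })

#' Construct an ImageTriplet
#'
#' @param image numeric matrix or H x W x 3 array.
#' @param groundTruth binary matrix, same height/width.
#' @param fov binary matrix, same height/width.
#' @param id character identifier.
#' @return An [ImageTriplet-class] object.
#' @examples
#' tr <- ImageTriplet(matrix(0, 8, 8), matrix(0, 8, 8),
#'                    matrix(1, 8, 8), "blank")
#' @export
ImageTriplet <- function(image, groundTruth, fov, id = "img") {
  if (is.matrix(image)) storage.mode(image) <- "double"
  new("ImageTriplet", image = image,
      groundTruth = matrix(as.numeric(groundTruth), nrow(groundTruth)),
      fov = matrix(as.numeric(fov), nrow(fov)), id = id)
}

#' PatchGeometry: patch and stride sizes for tiling
#'
#' Governs both random training-patch extraction and the deterministic
#' overlapping test tiling. Full coverage of the tiled region requires the
#' stride not to exceed the patch size, which the validity method enforces.
#'
#' @slot patchH,patchW integer patch height/width in pixels.
#' @slot strideH,strideW integer tiling strides in pixels.
#' @export
setClass("PatchGeometry",
  representation(patchH = "integer", patchW = "integer",
                 strideH = "integer", strideW = "integer"),
  validity = function(object) {
    v <- c(object@patchH, object@patchW, object@strideH, object@strideW)
    if (any(v < 1L)) return("all geometry fields must be >= 1")
    if (object@strideH > object@patchH || object@strideW > object@patchW)
      return("stride must not exceed patch size")
    TRUE
  })

#' Construct a PatchGeometry
#'
#' @param patchH,patchW patch size in pixels (default 48, the training and
#'   inference patch resolution).
#' @param strideH,strideW tiling stride in pixels (default 5).
#' @return A [PatchGeometry-class] object.
#' @examples
#' PatchGeometry(48, 48, 5, 5)
#' @export
PatchGeometry <- function(patchH = 48L, patchW = patchH,
                          strideH = 5L, strideW = strideH) {
  new("PatchGeometry", patchH = as.integer(patchH), patchW = as.integer(patchW),
      strideH = as.integer(strideH), strideW = as.integer(strideW))
}

#' PatchSet: an ordered collection of same-sized patches
#'
#' @slot patches numeric array (patchH x patchW x n).
#' @slot centers integer matrix (n x 2) of 1-based (row, col) patch centers
#'   in the source-image frame.
#' @slot sourceId character identifier of the source image.
#' @slot ordering `"random"` for sampled patches, `"raster"` for the
#'   deterministic tiling (rows outer, columns inner).
#' @export
setClass("PatchSet",
  representation(patches = "array", centers = "matrix",
                 sourceId = "character", ordering = "character"),
  validity = function(object) {
    if (length(dim(object@patches)) != 3L)
      return("patches must be a 3-d array (h x w x n)")
    if (dim(object@patches)[3] != nrow(object@centers))
      return("number of patches and centers differ")
    if (!object@ordering %in% c("random", "raster"))
      return("ordering must be 'random' or 'raster'")
    TRUE
  })

PatchSet <- function(patches, centers, sourceId = "img", ordering = "random") {
  new("PatchSet", patches = patches,
      centers = matrix(as.integer(centers), ncol = 2),
      sourceId = sourceId, ordering = ordering)
}

#' NormalizationStats: dataset-level intensity moments
#'
#' Pooled mean and standard deviation over every pixel of every training
#' image, used to standardize both training and test images
#' (`(X - mu) / sigma`).
#'
#' @slot mu pooled mean intensity.
#' @slot sigma pooled (population) standard deviation; must be positive.
#' @export
setClass("NormalizationStats",
  representation(mu = "numeric", sigma = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    TRUE
  })

#' @rdname NormalizationStats-class
#' @param mu,sigma pooled mean / standard deviation.
#' @export
NormalizationStats <- function(mu, sigma)
  new("NormalizationStats", mu = as.numeric(mu), sigma = as.numeric(sigma))

#' NetworkConfig: dense U-net hyper-parameters
#'
#' @slot growthRate feature maps added per dense-block layer (k).
#' @slot initChannels channels produced by the stem convolution (k0).
#' @slot nDenseBlocks dense blocks per path; the patch is downsampled 2x per
#'   block, so `patchSize` must be divisible by `2^nDenseBlocks`.
#' @slot layersPerBlock composite layers per dense block (l).
#' @slot patchSize input spatial size.
#' @slot dropout dropout rate inside dense-block layers.
#' @slot upsampleMode `"bilinear"` or `"nearest"` transition-up
#'   interpolation.
#' @export
setClass("NetworkConfig",
  representation(growthRate = "integer", initChannels = "integer",
                 nDenseBlocks = "integer", layersPerBlock = "integer",
                 patchSize = "integer", dropout = "numeric",
                 upsampleMode = "character"),
  validity = function(object) {
    if (object@growthRate < 1L) return("growthRate must be >= 1")
    if (object@layersPerBlock < 1L) return("layersPerBlock must be >= 1")
    if (object@nDenseBlocks < 1L) return("nDenseBlocks must be >= 1")
    if (object@initChannels < 1L) return("initChannels must be >= 1")
    if (object@patchSize %% (2L^object@nDenseBlocks) != 0L)
      return("patchSize must be divisible by 2^nDenseBlocks")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must be in [0, 1)")
    if (!object@upsampleMode %in% c("bilinear", "nearest"))
      return("upsampleMode must be 'bilinear' or 'nearest'")
    TRUE
  })

#' Construct a NetworkConfig
#'
#' Defaults follow the standard training configuration for this
#' architecture (growth rate 16, two dense blocks of five layers, 48 x 48
#' patches); the stem width and dropout rate are package choices, sized so
#' the model trains in reasonable time on a single CPU core (see the
#' methods vignette).
#'
#' @param growthRate feature maps added per dense layer.
#' @param initChannels stem convolution output channels.
#' @param nDenseBlocks dense blocks per path.
#' @param layersPerBlock layers per dense block.
#' @param patchSize input spatial size.
#' @param dropout dropout rate in dense-block layers.
#' @param upsampleMode transition-up interpolation.
#' @return A [NetworkConfig-class] object.
#' @examples
#' NetworkConfig()
#' @export
NetworkConfig <- function(growthRate = 16L, initChannels = 8L,
                          nDenseBlocks = 2L, layersPerBlock = 5L,
                          patchSize = 48L, dropout = 0.2,
                          upsampleMode = "bilinear") {
  new("NetworkConfig", growthRate = as.integer(growthRate),
      initChannels = as.integer(initChannels),
      nDenseBlocks = as.integer(nDenseBlocks),
      layersPerBlock = as.integer(layersPerBlock),
      patchSize = as.integer(patchSize), dropout = dropout,
      upsampleMode = upsampleMode)
}

#' TrainConfig: optimization settings
#'
#' @slot epochs number of passes over the training patches.
#' @slot learningRate,momentum SGD settings (defaults 0.01 / 0.9).
#' @slot batchSize mini-batch size.
#' @slot validationFraction fraction of patches held out for validation.
#' @slot seed integer master seed for shuffling, init and dropout.
#' @slot lossKind `"dice"` or `"cross_entropy"`.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric",
                 momentum = "numeric", batchSize = "integer",
                 validationFraction = "numeric", seed = "integer",
                 lossKind = "character"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@validationFraction <= 0 || object@validationFraction >= 1)
      return("validationFraction must be in (0, 1)")
    if (!object@lossKind %in% c("dice", "cross_entropy"))
      return("lossKind must be 'dice' or 'cross_entropy'")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    TRUE
  })

#' Construct a TrainConfig
#'
#' @param epochs training epochs.
#' @param learningRate,momentum SGD hyper-parameters.
#' @param batchSize mini-batch size.
#' @param validationFraction held-out patch fraction.
#' @param seed integer seed.
#' @param lossKind `"dice"` or `"cross_entropy"`.
#' @return A [TrainConfig-class] object.
#' @examples
#' TrainConfig(epochs = 5)
#' @export
TrainConfig <- function(epochs = 150L, learningRate = 0.01, momentum = 0.9,
                        batchSize = 16L, validationFraction = 0.1,
                        seed = 1L, lossKind = "dice") {
  new("TrainConfig", epochs = as.integer(epochs), learningRate = learningRate,
      momentum = momentum, batchSize = as.integer(batchSize),
      validationFraction = validationFraction, seed = as.integer(seed),
      lossKind = lossKind)
}

#' AccumulatorPair: running sums for overlapping-tile reconstruction
#'
#' `fullPro` holds the per-pixel sum of predicted probabilities and
#' `fullSum` the per-pixel visit count over all overlapping patches.
#'
#' @slot fullPro numeric matrix of summed probabilities.
#' @slot fullSum numeric matrix of visit counts.
#' @export
setClass("AccumulatorPair",
  representation(fullPro = "matrix", fullSum = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@fullPro), dim(object@fullSum)))
      return("fullPro and fullSum sizes differ")
    if (any(object@fullSum < 0)) return("fullSum must be non-negative")
    if (any(object@fullPro[object@fullSum == 0] != 0))
      return("fullPro must be 0 where fullSum is 0")
    if (any(object@fullPro > object@fullSum + 1e-9))
      return("fullPro cannot exceed fullSum (probabilities are <= 1)")
    TRUE
  })

#' ProbabilityMap: reconstructed vessel probability image
#'
#' @slot values numeric matrix in `[0, 1]`; uncovered pixels are 0.
#' @slot coverage logical matrix, TRUE where at least one patch visited.
#' @export
setClass("ProbabilityMap",
  representation(values = "matrix", coverage = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@values), dim(object@coverage)))
      return("values and coverage sizes differ")
    v <- object@values[object@coverage]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      return("covered probabilities must lie in [0, 1]")
    TRUE
  })

#' ConfusionCounts: FOV-restricted pixel confusion matrix
#'
#' @slot tp,fn,tn,fp pixel counts within the evaluation mask.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fn = "numeric", tn = "numeric",
                 fp = "numeric"),
  validity = function(object) {
    if (any(c(object@tp, object@fn, object@tn, object@fp) < 0))
      return("counts must be non-negative")
    TRUE
  })

#' MetricReport: segmentation metrics inside the evaluation mask
#'
#' @slot se,sp,acc,auc sensitivity, specificity, accuracy and ROC AUC
#'   (NA when undefined for a degenerate mask).
#' @slot threshold binarization threshold used for Se/Sp/Acc.
#' @slot nPixels number of evaluated pixels.
#' @slot counts the underlying [ConfusionCounts-class].
#' @export
setClass("MetricReport",
  representation(se = "numeric", sp = "numeric", acc = "numeric",
                 auc = "numeric", threshold = "numeric", nPixels = "numeric",
                 counts = "ConfusionCounts"))

#' PhantomSpec: synthetic fundus-triplet generator settings
#'
#' Describes a vascular phantom: a circular FOV containing a branching
#' random-walk vessel tree 1-4 px wide, rendered onto a smooth background
#' with Gaussian noise. Signed `contrast` selects dark-on-bright vessels
#' (negative, the fundus convention) or bright-on-dark (positive).
#'
#' @slot height,width image size in pixels.
#' @slot fovRadiusFrac FOV radius as a fraction of `min(height, width)/2`.
#' @slot nTrees number of root vessels.
#' @slot branchProb per-step bifurcation probability.
#' @slot widthRange vessel width range in pixels (within 1-4).
#' @slot contrast signed vessel-background intensity difference.
#' @slot noiseSd Gaussian pixel-noise standard deviation.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 fovRadiusFrac = "numeric", nTrees = "integer",
                 branchProb = "numeric", widthRange = "numeric",
                 contrast = "numeric", noiseSd = "numeric"),
  validity = function(object) {
    if (object@height < 32L || object@width < 32L)
      return("phantom must be at least 32 x 32")
    if (object@fovRadiusFrac <= 0 || object@fovRadiusFrac > 1)
      return("fovRadiusFrac must be in (0, 1]")
    if (length(object@widthRange) != 2L || any(object@widthRange < 1) ||
        any(object@widthRange > 4) ||
        object@widthRange[1] > object@widthRange[2])
      return("widthRange must be increasing within [1, 4]")
    if (object@nTrees < 1L) return("nTrees must be >= 1")
    if (object@branchProb < 0 || object@branchProb > 1)
      return("branchProb must be in [0, 1]")
    TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults produce 128 x 128 phantoms with dark vessels on a bright
#' background whose vessel fraction inside the FOV falls in the 5-20% band
#' typical of fundus photographs.
#'
#' @param height,width image size.
#' @param fovRadiusFrac FOV radius fraction.
#' @param nTrees root vessel count.
#' @param branchProb per-step bifurcation probability.
#' @param widthRange vessel width range (px).
#' @param contrast signed vessel contrast.
#' @param noiseSd background noise sd.
#' @return A [PhantomSpec-class] object.
#' @examples
#' PhantomSpec()
#' @export
PhantomSpec <- function(height = 128L, width = 128L, fovRadiusFrac = 0.92,
                        nTrees = 5L, branchProb = 0.04,
                        widthRange = c(1, 4), contrast = -90,
                        noiseSd = 8) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      fovRadiusFrac = fovRadiusFrac, nTrees = as.integer(nTrees),
      branchProb = branchProb, widthRange = as.numeric(widthRange),
      contrast = contrast, noiseSd = noiseSd)
}

#' VesselNet: a trainable segmentation network
#'
#' Wraps the parameter tensors, batch-norm running statistics and the
#' analytic layer descriptor (model spec) of either the dense U-net or the
#' plain U-net baseline. Parameters live in nested R lists of arrays;
#' the forward/backward passes are driven by the architecture tag.
#'
#' @slot arch `"dense_unet"` or `"unet"`.
#' @slot config a [NetworkConfig-class] (dense U-net) as built.
#' @slot params nested list of weight arrays.
#' @slot state nested list of batch-norm running means/variances.
#' @slot spec analytic ModelSpec: layer table and channel traces.
#' @export
setClass("VesselNet",
  representation(arch = "character", config = "NetworkConfig",
                 params = "list", state = "list", spec = "list"))

#' LossReport: per-epoch training history
#'
#' @slot trainLoss,valLoss,valDice numeric vectors, one entry per epoch.
#' @slot bestEpoch epoch with the highest validation dice.
#' @slot seed seed used for the run.
#' @export
setClass("LossReport",
  representation(trainLoss = "numeric", valLoss = "numeric",
                 valDice = "numeric", bestEpoch = "integer",
                 seed = "integer"),
  validity = function(object) {
    n <- length(object@trainLoss)
    if (length(object@valLoss) != n || length(object@valDice) != n)
      return("history vectors must have equal length")
    TRUE
  })

#' RunConfig: one experiment, end to end
#'
#' Aggregates everything a `simulate` / `train` / `predict` / `evaluate`
#' pipeline run needs; serializes losslessly to JSON.
#'
#' @slot dataDir dataset directory (written by `simulate` or DRIVE-style).
#' @slot layout `"flat"` or `"drive"`.
#' @slot outDir output directory for artifacts.
#' @slot phantom [PhantomSpec-class] used by `simulate`.
#' @slot nPhantoms,nTest phantom counts (total / held out for testing).
#' @slot geometry [PatchGeometry-class].
#' @slot network [NetworkConfig-class].
#' @slot train [TrainConfig-class].
#' @slot nPatches total random training patches.
#' @slot augment logical, elastic augmentation on/off.
#' @slot augSigma,augAlpha displacement-field smoothing scale / amplitude.
#' @slot grayscaleMode `"luminance"` or `"green"`.
#' @slot threshold probability binarization threshold.
#' @slot seed master seed; every stage derives its own stream from it.
#' @export
setClass("RunConfig",
  representation(dataDir = "character", layout = "character",
                 outDir = "character", phantom = "PhantomSpec",
                 nPhantoms = "integer", nTest = "integer",
                 geometry = "PatchGeometry", network = "NetworkConfig",
                 train = "TrainConfig", nPatches = "integer",
                 augment = "logical", augSigma = "numeric",
                 augAlpha = "numeric", grayscaleMode = "character",
                 threshold = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@layout %in% c("flat", "drive"))
      return("layout must be 'flat' or 'drive'")
    if (!object@grayscaleMode %in% c("luminance", "green"))
      return("grayscaleMode must be 'luminance' or 'green'")
    TRUE
  })

#' Construct a RunConfig
#'
#' @param dataDir,outDir dataset / output directories.
#' @param layout dataset layout.
#' @param phantom phantom generator spec.
#' @param nPhantoms,nTest phantoms to simulate / hold out.
#' @param geometry patch geometry.
#' @param network network configuration.
#' @param train training configuration.
#' @param nPatches total random training patches.
#' @param augment enable elastic augmentation.
#' @param augSigma,augAlpha augmentation field scale / amplitude (px).
#' @param grayscaleMode color-to-gray conversion.
#' @param threshold binarization threshold.
#' @param seed master seed.
#' @return A [RunConfig-class] object.
#' @examples
#' cfg <- RunConfig(dataDir = tempfile(), outDir = tempfile())
#' @export
RunConfig <- function(dataDir, outDir, layout = "flat",
                      phantom = PhantomSpec(), nPhantoms = 12L, nTest = 3L,
                      geometry = PatchGeometry(), network = NetworkConfig(),
                      train = TrainConfig(), nPatches = 500L,
                      augment = FALSE, augSigma = 4, augAlpha = 8,
                      grayscaleMode = "luminance", threshold = 0.5,
                      seed = 1L) {
  new("RunConfig", dataDir = dataDir, layout = layout, outDir = outDir,
      phantom = phantom, nPhantoms = as.integer(nPhantoms),
      nTest = as.integer(nTest), geometry = geometry, network = network,
      train = train, nPatches = as.integer(nPatches), augment = augment,
      augSigma = augSigma, augAlpha = augAlpha,
      grayscaleMode = grayscaleMode, threshold = threshold,
      seed = as.integer(seed))
}
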