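#' @include io.R
NULL

# per-stage seeds derived from the master seed
.stageSeeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("simulate", "sampling", "training", "predict")
  s
}

.trainTestSplit <- function(triplets, nTest) {
  n <- length(triplets)
  if (nTest >= n) stop("nTest must leave at least one training image")
  list(train = triplets[seq_len(n - nTest)],
       test = if (nTest > 0) triplets[(n - nTest + 1L):n] else list())
}

.checkpointPath <- function(outDir) file.path(outDir, "checkpoint.rds")

.pipelineSimulate <- function(config, seeds, verbose) {
  triplets <- generatePhantomDataset(config@nPhantoms, config@phantom,
                                     seed = seeds[["simulate"]])
  for (tr in triplets) writeTriplet(tr, config@dataDir)
  if (verbose)
    message("simulate: wrote ", length(triplets), " phantom triplets to ",
            config@dataDir)
  invisible(triplets)
}

.pipelineTrain <- function(config, seeds, verbose) {
  triplets <- loadDataset(config@dataDir, config@layout)
  split <- .trainTestSplit(triplets, config@nTest)
  gray <- lapply(split$train, function(tr)
    toGrayscale(tr@image, config@grayscaleMode))
  stats <- computeDatasetStats(gray)
  geom <- config@geometry

  perImage <- patchesPerImage(config@nPatches, length(split$train))
  set.seed(seeds[["sampling"]])
  srcList <- list(); gndList <- list()
  for (i in seq_along(split$train)) {
    tr <- split$train[[i]]
    norm <- ImageTriplet(normalizeImage(gray[[i]], stats), tr@groundTruth,
                         tr@fov, tr@id)
    ps <- sampleRandomPatches(norm, perImage, geom)
    srcList[[i]] <- ps$source@patches
    gndList[[i]] <- ps$ground@patches
  }
  d <- c(geom@patchH, geom@patchW)
  src <- array(unlist(srcList), c(d, perImage * length(srcList)))
  gnd <- array(unlist(gndList), c(d, perImage * length(gndList)))
  if (config@augment) {
    aug <- augmentPatchSet(PatchSet(src, matrix(0L, dim(src)[3], 2)),
                           PatchSet(gnd, matrix(0L, dim(gnd)[3], 2)),
                           config@augSigma, config@augAlpha)
    src <- aug$source@patches
    gnd <- aug$ground@patches
  }
  if (verbose)
    message("train: ", dim(src)[3], " patches of ", d[1], " x ", d[2],
            " from ", length(split$train), " images")

  set.seed(seeds[["training"]])
  net <- buildDenseUnet(config@network)
  if (verbose) {
    message("train: dense U-net with ",
            format(countParameters(net), big.mark = ","), " parameters")
    sp <- modelSpec(net)$layers
    message("train: channel trace ",
            paste(sp$outChannels, collapse = " > "))
  }
  tc <- config@train
  tc@seed <- seeds[["training"]]
  fit <- trainNetwork(net, src, gnd, tc, verbose = verbose)

  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(net = fit$net, stats = stats), .checkpointPath(config@outDir))
  write.csv(data.frame(epoch = seq_along(fit$report@trainLoss),
                       trainLoss = fit$report@trainLoss,
                       valLoss = fit$report@valLoss,
                       valDice = fit$report@valDice),
            file.path(config@outDir, "loss_history.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mu = stats@mu, sigma = stats@sigma,
         nPatches = dim(src)[3], nParameters = countParameters(net),
         bestEpoch = fit$report@bestEpoch,
         bestValDice = max(fit$report@valDice)),
    file.path(config@outDir, "train_manifest.json"), auto_unbox = TRUE,
    digits = NA)
  writeRunConfig(config, file.path(config@outDir, "run_config.json"))
  invisible(fit)
}

.pipelinePredict <- function(config, seeds, verbose) {
  ck <- .checkpointPath(config@outDir)
  if (!file.exists(ck))
    stop("no checkpoint under ", config@outDir, "; run the 'train' stage first")
  saved <- readRDS(ck)
  triplets <- loadDataset(config@dataDir, config@layout)
  split <- .trainTestSplit(triplets, config@nTest)
  if (!length(split$test)) stop("nTest is 0: nothing to predict")
  maps <- list()
  for (tr in split$test) {
    gray <- toGrayscale(tr@image, config@grayscaleMode)
    norm <- normalizeImage(gray, saved$stats)
    tiles <- extractOverlapPatches(norm, config@geometry)
    preds <- predictPatches(saved$net, tiles, config@train@batchSize)
    pmap <- reconstructMap(preds, config@geometry, nrow(norm), ncol(norm))
    writeProbabilityMap(pmap,
                        file.path(config@outDir, paste0(tr@id, "_prob.png")),
                        file.path(config@outDir, paste0(tr@id, "_prob.bin")))
    writeImageRaster(binarizeMap(pmap, config@threshold),
                     file.path(config@outDir, paste0(tr@id, "_bin.png")),
                     maxValue = 1)
    maps[[tr@id]] <- pmap
    if (verbose) message("predict: reconstructed ", tr@id)
  }
  invisible(maps)
}

.pipelineEvaluate <- function(config, seeds, verbose) {
  triplets <- loadDataset(config@dataDir, config@layout)
  split <- .trainTestSplit(triplets, config@nTest)
  reports <- list()
  for (tr in split$test) {
    binPath <- file.path(config@outDir, paste0(tr@id, "_prob.bin"))
    if (!file.exists(binPath))
      stop("no prediction for ", tr@id, " under ", config@outDir,
           "; run the 'predict' stage first")
    pmap <- readProbabilityMap(binPath)
    reports[[tr@id]] <- evaluateMap(pmap, tr@groundTruth, tr@fov,
                                    config@threshold)
  }
  tab <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(id = id, se = r@se, sp = r@sp, acc = r@acc, auc = r@auc)
  }))
  mean_row <- data.frame(id = "mean", se = mean(tab$se), sp = mean(tab$sp),
                         acc = mean(tab$acc), auc = mean(tab$auc))
  jsonlite::write_json(
    list(perImage = tab, mean = as.list(mean_row[-1]),
         threshold = config@threshold),
    file.path(config@outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (verbose) {
    out <- rbind(tab, mean_row)
    message(paste(utils::capture.output(print(out, row.names = FALSE,
                                              digits = 4)),
                  collapse = "\n"))
  }
  attr(reports, "mean") <- mean_row
  invisible(reports)
}

#' Run a pipeline stage
#'
#' Executes one stage of the experiment described by a
#' [RunConfig-class]: `"simulate"` writes phantom triplets to the dataset
#' directory; `"train"` runs preprocessing, FOV-constrained patch sampling,
#' optional elastic augmentation and SGD training, persisting the
#' checkpoint, normalization statistics and loss history; `"predict"`
#' tiles the held-out images, runs inference and reconstructs probability
#' maps (PNG + lossless dump); `"evaluate"` computes FOV-masked Se/Sp/Acc
#' and AUC per held-out image plus their mean. `"all"` runs the four in
#' order. All randomness is derived from `config@seed`, one substream per
#' stage, so a full re-run reproduces identical metrics.
#'
#' @param config a [RunConfig-class].
#' @param command one of `"simulate"`, `"train"`, `"predict"`,
#'   `"evaluate"`, `"all"`.
#' @param verbose log stage progress.
#' @return stage-dependent, invisibly: triplets (`simulate`), fit
#'   (`train`), probability maps (`predict`), or a list of
#'   [MetricReport-class] objects with a `mean` attribute (`evaluate` and
#'   `all`).
#' @export
runPipeline <- function(config,
                        command = c("all", "simulate", "train", "predict",
                                    "evaluate"),
                        verbose = FALSE) {
  stopifnot(is(config, "RunConfig"))
  command <- match.arg(command)
  seeds <- .stageSeeds(config@seed)
  switch(command,
    simulate = .pipelineSimulate(config, seeds, verbose),
    train = .pipelineTrain(config, seeds, verbose),
    predict = .pipelinePredict(config, seeds, verbose),
    evaluate = .pipelineEvaluate(config, seeds, verbose),
    all = {
      .pipelineSimulate(config, seeds, verbose)
      .pipelineTrain(config, seeds, verbose)
      .pipelinePredict(config, seeds, verbose)
      .pipelineEvaluate(config, seeds, verbose)
    })
}
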