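#' @include AllClasses.R
NULL

# ---- raster I/O ----------------------------------------------------------

.readPNM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  tokens <- integer(0)
  # header tokens: width, height, maxval (comments allowed)
  readTok <- function() {
    repeat {
      ch <- readChar(con, 1)
      while (length(ch) && grepl("^\\s$", ch)) ch <- readChar(con, 1)
      if (!length(ch)) stop("truncated PNM header in ", path)
      if (ch == "#") {
        while (length(ch) && ch != "\n") ch <- readChar(con, 1)
        next
      }
      tok <- ch
      repeat {
        ch <- readChar(con, 1)
        if (!length(ch) || grepl("^\\s$", ch)) break
        tok <- paste0(tok, ch)
      }
      return(as.integer(tok))
    }
  }
  w <- readTok(); h <- readTok(); maxval <- readTok()
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    size <- if (maxval > 255) 2L else 1L
    as.numeric(readBin(con, "integer", n, size = size, signed = FALSE,
                       endian = "big"))
  } else {
    as.numeric(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  vals <- vals * (255 / maxval)
  if (nch == 1L) {
    matrix(vals, h, w, byrow = TRUE) # PNM is row-major
  } else {
    a <- array(0, c(h, w, 3))
    for (c in 1:3)
      a[, , c] <- matrix(vals[seq(c, n, by = 3)], h, w, byrow = TRUE)
    a
  }
}

#' Read a raster image as a matrix or array in `[0, 255]`
#'
#' PNG/TIFF/JPEG are read through EBImage; PGM/PPM (ASCII and binary PNM)
#' through a built-in reader. GIF is not supported by any installed
#' reader and raises a descriptive error.
#'
#' @param path image file.
#' @return numeric matrix (H x W) or array (H x W x 3), intensities in
#'   `[0, 255]`.
#' @export
readImageRaster <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gif")
    stop("GIF is not supported (no installed reader); convert ", path,
         " to PNG or TIFF")
  if (ext %in% c("pgm", "ppm", "pnm")) return(.readPNM(path))
  img <- EBImage::readImage(path)
  d <- dim(img)
  dat <- EBImage::imageData(img) * 255
  if (length(d) == 2L) return(t(dat))
  if (d[3] >= 3L) {
    out <- array(0, c(d[2], d[1], 3))
    for (c in 1:3) out[, , c] <- t(dat[, , c])
    return(out)
  }
  t(dat[, , 1])
}

#' Write a matrix or array as a raster image
#'
#' @param x numeric matrix (H x W) or array (H x W x 3) with intensities in
#'   `[0, maxValue]`.
#' @param path output file; the extension selects the format (png/tiff/jpg).
#' @param maxValue intensity full scale (255 for images, 1 for probability
#'   maps).
#' @return invisibly, `path`.
#' @export
writeImageRaster <- function(x, path, maxValue = 255) {
  v <- pmin(pmax(x / maxValue, 0), 1)
  img <- if (is.matrix(v)) {
    EBImage::Image(t(v), colormode = "Grayscale")
  } else {
    a <- array(0, c(dim(v)[2], dim(v)[1], 3))
    for (c in 1:3) a[, , c] <- t(v[, , c])
    EBImage::Image(a, colormode = "Color")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

# ---- dataset readers -----------------------------------------------------

.binarizeMask <- function(m, file) {
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.numeric(m > 127), nrow(m), ncol(m))
}

.readTripletFiles <- function(imgFile, gtFile, fovFile, id) {
  img <- readImageRaster(imgFile)
  gt <- .binarizeMask(readImageRaster(gtFile), gtFile)
  fov <- .binarizeMask(readImageRaster(fovFile), fovFile)
  if (!identical(dim(img)[1:2], dim(gt)))
    stop("size mismatch between ", imgFile, " and ", gtFile)
  if (!identical(dim(img)[1:2], dim(fov)))
    stop("size mismatch between ", imgFile, " and ", fovFile)
  ImageTriplet(img, gt, fov, id)
}

#' Load a dataset of image/ground-truth/FOV triplets
#'
#' Two layouts are understood. `"flat"` (written by the `simulate`
#' pipeline stage): one directory with `<id>_img.png`, `<id>_gt.png` and
#' `<id>_fov.png` per triplet. `"drive"`: the DRIVE-style tree with
#' `images/`, `1st_manual/` and `mask/` subdirectories, files matched by
#' the numeric stem before the first underscore. Ground truth and FOV are
#' binarized at intensity > 127. Triplets are returned in lexicographic
#' stem order; a missing ground truth or FOV file is a per-file error
#' (never a silent all-ones mask).
#'
#' @param root dataset directory.
#' @param layout `"flat"` or `"drive"`.
#' @return list of [ImageTriplet-class] objects.
#' @export
loadDataset <- function(root, layout = c("flat", "drive")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("dataset directory does not exist: ", root)
  if (layout == "flat") {
    imgs <- sort(list.files(root, pattern = "_img\\.(png|tif|tiff|jpg|jpeg|pgm|ppm)$"))
    if (!length(imgs)) stop("no *_img.* files under ", root)
    lapply(imgs, function(f) {
      stem <- sub("_img\\.[^.]+$", "", f)
      ext <- tools::file_ext(f)
      gtF <- file.path(root, paste0(stem, "_gt.", ext))
      fovF <- file.path(root, paste0(stem, "_fov.", ext))
      if (!file.exists(gtF)) stop("missing ground truth for ", f, ": ", gtF)
      if (!file.exists(fovF)) stop("missing FOV mask for ", f, ": ", fovF)
      .readTripletFiles(file.path(root, f), gtF, fovF, stem)
    })
  } else {
    imgDir <- file.path(root, "images")
    gtDir <- file.path(root, "1st_manual")
    fovDir <- file.path(root, "mask")
    for (d in c(imgDir, gtDir, fovDir))
      if (!dir.exists(d)) stop("missing subdirectory: ", d)
    imgs <- sort(list.files(imgDir))
    if (!length(imgs)) stop("no images under ", imgDir)
    lapply(imgs, function(f) {
      stem <- sub("_.*$", "", tools::file_path_sans_ext(f))
      findOne <- function(dir, what) {
        hit <- list.files(dir, pattern = paste0("^", stem, "[_.]"))
        if (!length(hit)) stop("missing ", what, " for ", f, " under ", dir)
        file.path(dir, sort(hit)[1])
      }
      .readTripletFiles(file.path(imgDir, f), findOne(gtDir, "ground truth"),
                        findOne(fovDir, "FOV mask"), stem)
    })
  }
}

#' Write an ImageTriplet as flat-layout PNG files
#'
#' @param triplet an [ImageTriplet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths written.
#' @export
writeTriplet <- function(triplet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- triplet@id
  p <- file.path(dir, paste0(id, c("_img.png", "_gt.png", "_fov.png")))
  writeImageRaster(triplet@image, p[1])
  writeImageRaster(255 * triplet@groundTruth, p[2])
  writeImageRaster(255 * triplet@fov, p[3])
  invisible(p)
}

# ---- RunConfig serialization ---------------------------------------------

.s4ToList <- function(x) {
  out <- lapply(slotNames(class(x)), function(nm) {
    v <- slot(x, nm)
    if (isVirtualClass(class(v)) || is(v, "PhantomSpec") ||
        is(v, "PatchGeometry") || is(v, "NetworkConfig") ||
        is(v, "TrainConfig")) .s4ToList(v) else v
  })
  names(out) <- slotNames(class(x))
  out
}

#' Serialize a RunConfig to JSON
#'
#' @param config a [RunConfig-class].
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  jsonlite::write_json(.s4ToList(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a RunConfig from JSON
#'
#' `readRunConfig(writeRunConfig(x))` reproduces `x` exactly.
#'
#' @param path JSON file written by [writeRunConfig()].
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  RunConfig(dataDir = j$dataDir, outDir = j$outDir, layout = j$layout,
            phantom = PhantomSpec(j$phantom$height, j$phantom$width,
                                  j$phantom$fovRadiusFrac, j$phantom$nTrees,
                                  j$phantom$branchProb, j$phantom$widthRange,
                                  j$phantom$contrast, j$phantom$noiseSd),
            nPhantoms = j$nPhantoms, nTest = j$nTest,
            geometry = PatchGeometry(j$geometry$patchH, j$geometry$patchW,
                                     j$geometry$strideH, j$geometry$strideW),
            network = NetworkConfig(j$network$growthRate,
                                    j$network$initChannels,
                                    j$network$nDenseBlocks,
                                    j$network$layersPerBlock,
                                    j$network$patchSize, j$network$dropout,
                                    j$network$upsampleMode),
            train = TrainConfig(j$train$epochs, j$train$learningRate,
                                j$train$momentum, j$train$batchSize,
                                j$train$validationFraction, j$train$seed,
                                j$train$lossKind),
            nPatches = j$nPatches, augment = j$augment,
            augSigma = j$augSigma, augAlpha = j$augAlpha,
            grayscaleMode = j$grayscaleMode, threshold = j$threshold,
            seed = j$seed)
}
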