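#' Read a fundus image
#'
#' Reads a raster file (TIFF, PPM, JPEG or PNG — the formats the public
#' fundus datasets ship in) into an `H x W x 3` array of intensities in
#' `[0, 1]`, row-major with origin at the top-left. Grayscale inputs are
#' replicated to three channels; an alpha channel, if present, is dropped.
#' Integer sample values are scaled by the format's maximum (255 for 8-bit,
#' 65535 for 16-bit).
#'
#' @param path path to a `.tif/.tiff`, `.ppm/.pgm`, `.jpg/.jpeg` or `.png`
#'   file.
#' @return numeric `H x W x 3` array in `[0, 1]`.
#' @examples
#' img <- array(runif(12), c(2, 2, 3))
#' f <- tempfile(fileext = ".png")
#' png::writePNG(img, f)
#' dim(readFundusImage(f))
#' @export
readFundusImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: no such file '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    ppm = ,
    pgm = ,
    pnm = readPNM(path),
    jpg = ,
    jpeg = {
      x <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores (x, y[, c]); transpose to row-major (y, x[, c])
      if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
    },
    stop("unsupported image format '.", ext, "' for '", path, "'",
      call. = FALSE)
  )
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  clamp01(img)
}

#' Read a binary mask file
#'
#' Reads a vessel or FOV annotation and binarises it at half the intensity
#' range (`> 0.5`), which absorbs compression artefacts in nominally binary
#' annotations.
#'
#' @param path raster file path.
#' @return binary `H x W` matrix, 1 = foreground.
#' @export
readMask <- function(path) {
  img <- readFundusImage(path)
  rebinarize(img[, , 1])
}

#' Write a binary mask as lossless PNG
#'
#' @param mask binary matrix.
#' @param path output path.
#' @return the path, invisibly. Reading the file back yields the identical
#'   binary matrix.
#' @export
writeMask <- function(mask, path) {
  assertBinary(mask)
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' Standardise a sample to the network input size
#'
#' Resizes the image with bilinear interpolation and the masks with
#' nearest-neighbour sampling followed by re-binarisation, to a square
#' `side x side` frame (the training convention standardises all datasets to
#' 512 x 512). The sample's `sourceResolution` is preserved so predictions
#' can be mapped back (see [runPredict()]).
#'
#' @param sample a [FundusSample-class].
#' @param side target side in px, divisible by 4.
#' @return the resized [FundusSample-class].
#' @export
resizeToInput <- function(sample, side = 512L) {
  side <- as.integer(side)
  if (side < 4L || side %% 4L != 0L)
    stop("input side must be divisible by 4 (two 2x poolings must invert ",
      "exactly); got ", side, call. = FALSE)
  d <- dim(sample@image)
  if (d[1] == side && d[2] == side) return(sample)
  img <- clamp01(bilinearResizeArray(sample@image, side, side))
  vm <- rebinarize(nnResizeMatrix(sample@vesselMask, side, side), 0.5)
  fm <- if (is.null(sample@fovMask)) NULL else
    rebinarize(nnResizeMatrix(sample@fovMask, side, side), 0.5)
  new("FundusSample", id = sample@id, image = img, vesselMask = vm,
    fovMask = fm, sourceResolution = sample@sourceResolution)
}

#' Build train/test splits for a dataset
#'
#' `fixed_train_test` returns the single declared partition (DRIVE 20/20,
#' HRF 36/9); `leave_one_out` returns one split per sample, testing that
#' sample and training on the remaining N-1 (STARE, CHASE_DB1 protocol).
#'
#' @param spec a [DatasetSpec-class].
#' @return list of `list(train = ids, test = ids)` pairs. For every pair the
#'   union covers all sample ids and the intersection is empty.
#' @export
makeSplits <- function(spec) {
  stopifnot(is(spec, "DatasetSpec"))
  validObject(spec)
  if (spec@splitMode == "fixed_train_test") {
    list(list(train = spec@trainIds, test = spec@testIds))
  } else {
    lapply(seq_along(spec@sampleIds), function(i)
      list(train = spec@sampleIds[-i], test = spec@sampleIds[i]))
  }
}

#' Read a dataset laid out on disk
#'
#' Expects parallel directories of images, vessel masks and (optionally) FOV
#' masks whose sorted file order aligns; sample ids are the image base names.
#'
#' @param imageDir,maskDir,fovDir directories; `fovDir = NULL` means no FOV
#'   masks (the FOV is then taken to be the full frame downstream).
#' @return list of [FundusSample-class].
#' @export
readDataset <- function(imageDir, maskDir, fovDir = NULL) {
  imgs <- sort(list.files(imageDir, full.names = TRUE))
  msks <- sort(list.files(maskDir, full.names = TRUE))
  if (length(imgs) == 0L)
    stop("no images found in '", imageDir, "'", call. = FALSE)
  if (length(imgs) != length(msks))
    stop("image/mask count mismatch: ", length(imgs), " vs ", length(msks),
      call. = FALSE)
  fovs <- if (is.null(fovDir)) NULL else sort(list.files(fovDir,
    full.names = TRUE))
  lapply(seq_along(imgs), function(i) {
    img <- readFundusImage(imgs[i])
    fundusSample(
      id = tools::file_path_sans_ext(basename(imgs[i])),
      image = img,
      vesselMask = readMask(msks[i]),
      fovMask = if (is.null(fovs)) NULL else readMask(fovs[i]),
      sourceResolution = dim(img)[1:2])
  })
}

#' @rdname accessors
#' @param object an object of the documented classes.
#' @export
setMethod("sampleId", "FundusSample", function(object) object@id)

#' @rdname accessors
#' @export
setMethod("fundusImage", "FundusSample", function(object) object@image)

#' @rdname accessors
#' @export
setMethod("vesselMask", "FundusSample", function(object) object@vesselMask)

#' @rdname accessors
#' @export
setMethod("fovMask", "FundusSample", function(object) object@fovMask)

#' @rdname accessors
#' @export
setMethod("sourceResolution", "FundusSample",
  function(object) object@sourceResolution)

setMethod("show", "FundusSample", function(object) {
  d <- dim(object@image)
  cat("FundusSample '", object@id, "': ", d[1], " x ", d[2],
    " RGB, vessel pixels: ", sum(object@vesselMask),
    if (is.null(object@fovMask)) ", no FOV mask" else
      paste0(", FOV pixels: ", sum(object@fovMask)),
    "\n", sep = "")
})
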