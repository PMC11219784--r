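#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' FundusSample: one fundus photograph with its annotations
#'
#' Container pairing an RGB fundus image with its binary vessel ground truth
#' and an optional field-of-view (FOV) mask marking the circular imaged
#' region. Images are stored row-major (`[row, col, channel]`), origin at the
#' top-left, intensities in `[0, 1]`; masks are `{0,1}` matrices with 1 =
#' vessel (or 1 = inside FOV).
#'
#' @slot id character sample identifier.
#' @slot image numeric `H x W x 3` array, values in `[0, 1]`.
#' @slot vesselMask binary `H x W` matrix.
#' @slot fovMask binary `H x W` matrix, or `NULL` when the whole frame is
#'   considered imaged.
#' @slot sourceResolution integer `(height, width)` of the file the sample was
#'   read from, kept so predictions can be mapped back to native resolution.
#'
#' @seealso [fundusSample()], [readFundusImage()], [resizeToInput()]
#' @export
setClass("FundusSample",
  representation(
    id = "character",
    image = "array",
    vesselMask = "matrix",
    fovMask = "matrixOrNULL",
    sourceResolution = "integer"
  )
)

setValidity("FundusSample", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (any(object@image < 0 | object@image > 1))
    msg <- c(msg, "image intensities must lie in [0, 1]")
  if (!identical(dim(object@vesselMask), d[1:2]))
    msg <- c(msg, "vesselMask dimensions must match image")
  if (!all(object@vesselMask %in% c(0, 1)))
    msg <- c(msg, "vesselMask must contain only {0, 1}")
  if (!is.null(object@fovMask)) {
    if (!identical(dim(object@fovMask), d[1:2]))
      msg <- c(msg, "fovMask dimensions must match image")
    if (!all(object@fovMask %in% c(0, 1)))
      msg <- c(msg, "fovMask must contain only {0, 1}")
  }
  if (length(object@sourceResolution) != 2L || any(object@sourceResolution < 1L))
    msg <- c(msg, "sourceResolution must be two positive integers")
  if (length(msg)) msg else TRUE
})

#' @describeIn FundusSample constructor.
#' @param id,image,vesselMask,fovMask,sourceResolution see slots.
#' @export
fundusSample <- function(id, image, vesselMask,
                         fovMask = NULL,
                         sourceResolution = dim(image)[1:2]) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  new("FundusSample",
    id = as.character(id), image = image,
    vesselMask = vesselMask, fovMask = fovMask,
    sourceResolution = as.integer(sourceResolution))
}

#' DatasetSpec: a named collection of samples and its evaluation protocol
#'
#' Describes how a dataset is split for training and testing: either a fixed
#' train/test partition (DRIVE's 20/20, HRF's 36/9) or leave-one-out
#' cross-validation (STARE, CHASE_DB1).
#'
#' @slot name dataset name.
#' @slot sampleIds ids of all samples.
#' @slot splitMode `"fixed_train_test"` or `"leave_one_out"`.
#' @slot trainIds,testIds the declared partition (fixed mode only).
#' @slot inputSize side length, in pixels, every image is standardised to
#'   before entering the network; must be divisible by 4 so the two 2x
#'   poolings invert exactly.
#' @export
setClass("DatasetSpec",
  representation(
    name = "character",
    sampleIds = "character",
    splitMode = "character",
    trainIds = "character",
    testIds = "character",
    inputSize = "integer"
  )
)

setValidity("DatasetSpec", function(object) {
  msg <- character()
  if (!object@splitMode %in% c("fixed_train_test", "leave_one_out"))
    msg <- c(msg, "splitMode must be 'fixed_train_test' or 'leave_one_out'")
  if (length(object@sampleIds) < 1L)
    msg <- c(msg, "dataset must contain at least one sample")
  if (object@splitMode == "leave_one_out" && length(object@sampleIds) < 2L)
    msg <- c(msg, "leave_one_out requires at least 2 samples")
  if (object@splitMode == "fixed_train_test") {
    if (!setequal(c(object@trainIds, object@testIds), object@sampleIds) ||
        length(intersect(object@trainIds, object@testIds)) > 0L)
      msg <- c(msg, "trainIds and testIds must partition sampleIds")
  }
  if (length(object@inputSize) != 1L || object@inputSize < 4L ||
      object@inputSize %% 4L != 0L)
    msg <- c(msg, "inputSize must be positive and divisible by 4")
  if (length(msg)) msg else TRUE
})

#' @describeIn DatasetSpec constructor.
#' @param name,sampleIds,splitMode,trainIds,testIds,inputSize see slots.
#' @export
datasetSpec <- function(name, sampleIds,
                        splitMode = c("fixed_train_test", "leave_one_out"),
                        trainIds = character(), testIds = character(),
                        inputSize = 512L) {
  splitMode <- match.arg(splitMode)
  new("DatasetSpec", name = name, sampleIds = as.character(sampleIds),
    splitMode = splitMode, trainIds = as.character(trainIds),
    testIds = as.character(testIds), inputSize = as.integer(inputSize))
}

#' AugmentationPolicy: the rotation/contrast expansion applied to training data
#'
#' Each training image is expanded into
#' `rotationCount + length(contrastFactors)` variants: rotations at multiples
#' of `rotationStep` degrees (identity included) plus one unrotated
#' contrast-scaled variant per factor. The defaults (36 rotations at 10
#' degrees, contrast factors 0.9 and 1.1) give the 38-fold expansion used for
#' training.
#'
#' @slot rotationStep rotation increment in degrees.
#' @slot rotationCount number of rotations, identity included.
#' @slot contrastFactors multiplicative contrast factors applied about the
#'   FOV mean intensity.
#' @slot seed integer seed (the policy is deterministic; the seed is recorded
#'   for provenance of any downstream shuffling).
#' @export
setClass("AugmentationPolicy",
  representation(
    rotationStep = "numeric",
    rotationCount = "integer",
    contrastFactors = "numeric",
    seed = "integer"
  )
)

setValidity("AugmentationPolicy", function(object) {
  msg <- character()
  if (object@rotationCount < 1L)
    msg <- c(msg, "rotationCount must be >= 1")
  if (object@rotationStep <= 0)
    msg <- c(msg, "rotationStep must be positive")
  if (object@rotationCount * object@rotationStep > 360)
    msg <- c(msg, "rotationCount * rotationStep must not exceed 360 degrees")
  if (any(object@contrastFactors <= 0))
    msg <- c(msg, "contrastFactors must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn AugmentationPolicy constructor; defaults give 38 variants.
#' @param rotationStep,rotationCount,contrastFactors,seed see slots.
#' @export
augmentationPolicy <- function(rotationStep = 10, rotationCount = 36L,
                               contrastFactors = c(0.9, 1.1), seed = 1L) {
  new("AugmentationPolicy", rotationStep = rotationStep,
    rotationCount = as.integer(rotationCount),
    contrastFactors = contrastFactors, seed = as.integer(seed))
}

#' ChannelPlan: per-stage channel widths of the network
#'
#' The published architecture fixes the topology (three encoder blocks with
#' two max-poolings, a two-stage multipath block, a bottleneck, three decoder
#' blocks with bidirectional skips) and a total budget of 0.172 million
#' trainable parameters; the per-stage widths are a free design choice under
#' that budget. The default plan (stem 8; encoder 8/16/32; multipath 32;
#' bottleneck 32; decoder 32/16/8) builds a network of 113,370 parameters.
#'
#' @slot stemChannels width of the stem convolution.
#' @slot encoderChannels widths of the three encoder blocks.
#' @slot multipathChannels width of every path of the multipath block (paths
#'   are summed elementwise, so all paths share one width).
#' @slot bottleneckChannels width of the bottleneck convolution.
#' @slot decoderChannels widths of the three decoder blocks.
#' @slot numClasses output classes of the softmax head (2: vessel/background).
#' @export
setClass("ChannelPlan",
  representation(
    stemChannels = "integer",
    encoderChannels = "integer",
    multipathChannels = "integer",
    bottleneckChannels = "integer",
    decoderChannels = "integer",
    numClasses = "integer"
  )
)

setValidity("ChannelPlan", function(object) {
  msg <- character()
  if (length(object@encoderChannels) != 3L)
    msg <- c(msg, "encoderChannels must have length 3")
  if (length(object@decoderChannels) != 3L)
    msg <- c(msg, "decoderChannels must have length 3")
  vals <- c(object@stemChannels, object@encoderChannels,
    object@multipathChannels, object@bottleneckChannels,
    object@decoderChannels, object@numClasses)
  if (any(vals < 1L)) msg <- c(msg, "all channel widths must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn ChannelPlan constructor with the default widths.
#' @param stemChannels,encoderChannels,multipathChannels,bottleneckChannels,decoderChannels,numClasses see slots.
#' @export
channelPlan <- function(stemChannels = 8L,
                        encoderChannels = c(8L, 16L, 32L),
                        multipathChannels = 32L,
                        bottleneckChannels = 32L,
                        decoderChannels = c(32L, 16L, 8L),
                        numClasses = 2L) {
  new("ChannelPlan", stemChannels = as.integer(stemChannels),
    encoderChannels = as.integer(encoderChannels),
    multipathChannels = as.integer(multipathChannels),
    bottleneckChannels = as.integer(bottleneckChannels),
    decoderChannels = as.integer(decoderChannels),
    numClasses = as.integer(numClasses))
}

#' LMBiSNet: a built network graph with weights
#'
#' Holds the ordered per-layer descriptor table (used for parameter
#' accounting and structural audits), the trainable weights, and the
#' batch-normalisation running statistics. Built by [buildNetwork()] or
#' [buildAblationVariant()]; run with [networkForward()]; trained with
#' [trainNetwork()].
#'
#' @slot plan the [ChannelPlan-class] the network was built from.
#' @slot variant one of `"full"`, `"lbl_mfeb"`, `"lightweight_baseline"`,
#'   `"baseline_unet"`.
#' @slot layers data.frame with one row per layer: name, kind, kernel,
#'   stride, inChannels, outChannels, params.
#' @slot weights named list of weight arrays.
#' @slot bnState named list of running mean/variance vectors per BN layer.
#' @slot inputChannels number of image channels expected (3).
#' @export
setClass("LMBiSNet",
  representation(
    plan = "ChannelPlan",
    variant = "character",
    layers = "data.frame",
    weights = "list",
    bnState = "list",
    inputChannels = "integer"
  )
)

#' TrainingConfig: optimisation schedule
#'
#' Dice loss, Adam with initial learning rate 0.001, a ceiling of 50 epochs,
#' learning-rate halving after 7 epochs without improvement of the monitored
#' validation dice, and early stopping.
#'
#' @slot initialLr initial Adam learning rate.
#' @slot maxEpochs epoch ceiling.
#' @slot plateauPatience stale epochs before the learning rate is halved.
#' @slot lrFactor multiplicative factor applied on plateau (0.5).
#' @slot earlyStopPatience stale epochs before training stops.
#' @slot batchSize images per optimizer step.
#' @slot seed controls weight init, data order, everything stochastic.
#' @export
setClass("TrainingConfig",
  representation(
    initialLr = "numeric",
    maxEpochs = "integer",
    plateauPatience = "integer",
    lrFactor = "numeric",
    earlyStopPatience = "integer",
    batchSize = "integer",
    seed = "integer"
  )
)

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@initialLr <= 0) msg <- c(msg, "initialLr must be positive")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@plateauPatience < 1L || object@earlyStopPatience < 1L)
    msg <- c(msg, "patiences must be >= 1")
  if (object@lrFactor <= 0 || object@lrFactor >= 1)
    msg <- c(msg, "lrFactor must lie in (0, 1)")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainingConfig constructor with the published schedule.
#' @param initialLr,maxEpochs,plateauPatience,lrFactor,earlyStopPatience,batchSize,seed see slots.
#' @export
trainingConfig <- function(initialLr = 0.001, maxEpochs = 50L,
                           plateauPatience = 7L, lrFactor = 0.5,
                           earlyStopPatience = 15L, batchSize = 2L,
                           seed = 1L) {
  new("TrainingConfig", initialLr = initialLr,
    maxEpochs = as.integer(maxEpochs),
    plateauPatience = as.integer(plateauPatience), lrFactor = lrFactor,
    earlyStopPatience = as.integer(earlyStopPatience),
    batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' SynthConfig: parameters of the synthetic fundus generator
#'
#' The generator emulates the features of a fundus photograph the pipeline
#' depends on: a circular field of view on a black background, a smooth
#' radial background gradient, and dark curvilinear branching vessel trees of
#' width about 1 to 8 pixels at 512 px.
#'
#' @slot side image side length in pixels, divisible by 4.
#' @slot nTrees number of vessel trees grown from the disc margin.
#' @slot branchDepth maximum bifurcation depth per tree.
#' @slot widthRange `(min, max)` vessel width in pixels at `side = 512`;
#'   widths scale with `side` and taper from max to min with depth.
#' @slot vesselContrast fractional darkening of vessel pixels, in `[0, 1]`.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot seed integer seed; generation is fully deterministic given it.
#' @export
setClass("SynthConfig",
  representation(
    side = "integer",
    nTrees = "integer",
    branchDepth = "integer",
    widthRange = "numeric",
    vesselContrast = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@side < 4L || object@side %% 4L != 0L)
    msg <- c(msg, "side must be positive and divisible by 4")
  if (object@nTrees < 0L) msg <- c(msg, "nTrees must be >= 0")
  if (length(object@widthRange) != 2L || any(object@widthRange <= 0) ||
      object@widthRange[1] > object@widthRange[2])
    msg <- c(msg, "widthRange must be an increasing positive pair")
  if (object@vesselContrast < 0 || object@vesselContrast > 1)
    msg <- c(msg, "vesselContrast must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SynthConfig constructor.
#' @param side,nTrees,branchDepth,widthRange,vesselContrast,noiseSd,seed see slots.
#' @export
synthConfig <- function(side = 512L, nTrees = 6L, branchDepth = 5L,
                        widthRange = c(1, 8), vesselContrast = 0.55,
                        noiseSd = 0.02, seed = 1L) {
  new("SynthConfig", side = as.integer(side), nTrees = as.integer(nTrees),
    branchDepth = as.integer(branchDepth), widthRange = as.numeric(widthRange),
    vesselContrast = vesselContrast, noiseSd = noiseSd,
    seed = as.integer(seed))
}

#' ConfusionCounts: pixelwise confusion tallies
#'
#' Pixel counts of true positives, true negatives, false positives and false
#' negatives over the evaluated region (inside the FOV when an FOV mask is
#' supplied). All five evaluation metrics derive from these four counts.
#'
#' @slot tp,tn,fp,fn non-negative pixel counts.
#' @seealso [confusionCounts()], [sensitivity()], [aucClosedForm()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@tn, object@fp, object@fn) < 0))
    "counts must be non-negative" else TRUE
})

#' MetricsReport: per-image metrics and their dataset mean
#'
#' @slot perImage data.frame with one row per image (id, Se, Sp, Acc, F1,
#'   AUC, as fractions in `[0,1]`).
#' @slot mean named numeric vector: unweighted mean over images, computed per
#'   metric over the images where it is defined.
#' @slot undefinedCounts named integer vector: how many per-image values were
#'   undefined (and so excluded) per metric.
#' @export
setClass("MetricsReport",
  representation(perImage = "data.frame", mean = "numeric",
    undefinedCounts = "integer"))
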