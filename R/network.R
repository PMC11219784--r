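# LMBiS-Net graph construction and execution.
#
# Topology (full variant), fixed by design; widths come from the ChannelPlan:
#
#   stem conv3x3
#   E1: conv3x3 -> ReLU -> BN          (full res)   --------+ forward skip
#     maxpool 2x2                                           |
#   E2: conv3x3 -> ReLU -> BN          (1/2 res)   ----+    |
#     maxpool 2x2                                      |    |
#   E3: conv3x3 -> ReLU -> BN          (1/4 res)       |    |
#   MFEB: two stages, each sum over k=1..3 of          |    |
#         BN(ReLU(conv n x n)), n = 2k-1 in {1,3,5}    |    |
#   bottleneck: conv3x3 -> ReLU -> BN                  |    |
#   D1: tconv2x2 /2 -> concat E2 -> conv3x3->ReLU->BN -+    |
#     reverse skip: 1x1 conv + 2x nearest upsample, added to E1
#   D2: tconv2x2 /2 -> concat refined E1 -> conv3x3 -> ReLU -> BN
#   D3: conv3x3 -> ReLU -> BN          (full res, no upsampling)
#   head: 1x1 conv -> softmax over classes
#
# Only two max-pool layers are used, so three encoder blocks pair with two
# strided upsamplings; D3 refines at full resolution. The operator order
# conv -> ReLU -> BN inside every block follows the block definition of the
# multipath stage (BN applied outside the activation).

PARAM_BUDGET <- 172000L

convParams <- function(k, cin, cout) k * k * cin * cout + cout
bnParams <- function(c) 2L * c

layerRow <- function(name, kind, kernel, stride, cin, cout, params) {
  data.frame(name = name, kind = kind, kernel = kernel, stride = stride,
    inChannels = cin, outChannels = cout, params = params,
    stringsAsFactors = FALSE)
}

# rows of the layer table + initialised weights for one conv->ReLU->BN block
blockLayers <- function(name, k, cin, cout) {
  rbind(
    layerRow(paste0(name, ".conv"), "conv", k, 1L, cin, cout,
      convParams(k, cin, cout)),
    layerRow(paste0(name, ".relu"), "relu", 0L, 1L, cout, cout, 0L),
    layerRow(paste0(name, ".bn"), "batchnorm", 0L, 1L, cout, cout,
      bnParams(cout)))
}

initBlock <- function(weights, bnState, name, k, cin, cout) {
  weights[[paste0(name, ".W")]] <- heConv(k, cin, cout)
  weights[[paste0(name, ".b")]] <- numeric(cout)
  weights[[paste0(name, ".gamma")]] <- rep(1, cout)
  weights[[paste0(name, ".beta")]] <- numeric(cout)
  bnState[[paste0(name, ".mean")]] <- numeric(cout)
  bnState[[paste0(name, ".var")]] <- rep(1, cout)
  bnState[[paste0(name, ".n")]] <- 0L
  list(weights = weights, bnState = bnState)
}

#' Build the LMBiS-Net computation graph
#'
#' Assembles the network under a channel plan: stem convolution, three
#' encoder blocks with max-pooling after the first two only, the two-stage
#' multipath feature-extraction block (parallel 1x1/3x3/5x5 paths, each
#' conv -> ReLU -> BN, summed elementwise), a bottleneck, three decoder
#' blocks (two transpose-convolution upsamplings restoring full resolution),
#' forward skip connections (E2 into D1, E1 into D2, merged by channel
#' concatenation) and a reverse skip remapping D1's decoded features back
#' onto the stored E1 features, and a softmax head. Weights are initialised
#' He-uniform under `seed`; batch-norm starts at scale 1 / shift 0 with
#' running statistics (0, 1).
#'
#' Building fails if the trainable-parameter total exceeds the 172,000 budget
#' the architecture is designed to respect; the error carries the per-layer
#' parameter table.
#'
#' @param plan a [ChannelPlan-class].
#' @param variant `"full"` (default), `"lbl_mfeb"` (no reverse skip),
#'   `"lightweight_baseline"` (no multipath block, no reverse skip), or
#'   `"baseline_unet"` (the heavy single-path reference; exempt from the
#'   budget).
#' @param seed integer controlling weight initialisation.
#' @param enforceBudget logical; the budget check (on by default except for
#'   `"baseline_unet"`).
#' @return an [LMBiSNet-class].
#' @examples
#' net <- buildNetwork(channelPlan(), seed = 1)
#' countParameters(net)
#' @export
buildNetwork <- function(plan = channelPlan(), variant = "full", seed = 1L,
                         enforceBudget = variant != "baseline_unet") {
  stopifnot(is(plan, "ChannelPlan"))
  validObject(plan)
  variant <- match.arg(variant,
    c("full", "lbl_mfeb", "lightweight_baseline", "baseline_unet"))
  hasMFEB <- variant %in% c("full", "lbl_mfeb")
  hasReverse <- variant == "full"

  st <- plan@stemChannels
  e <- plan@encoderChannels
  mp <- plan@multipathChannels
  bt <- plan@bottleneckChannels
  dc <- plan@decoderChannels
  nc <- plan@numClasses
  btIn <- if (hasMFEB) mp else e[3]

  weights <- list(); bnState <- list()
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  withSeed(seed, {
    weights[["stem.W"]] <- heConv(3L, 3L, st)
    weights[["stem.b"]] <- numeric(st)
    add(layerRow("stem.conv", "conv", 3L, 1L, 3L, st, convParams(3L, 3L, st)))

    ib <- initBlock(weights, bnState, "enc1", 3L, st, e[1])
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("enc1", 3L, st, e[1]))
    add(layerRow("pool1", "maxpool", 2L, 2L, e[1], e[1], 0L))

    ib <- initBlock(weights, bnState, "enc2", 3L, e[1], e[2])
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("enc2", 3L, e[1], e[2]))
    add(layerRow("pool2", "maxpool", 2L, 2L, e[2], e[2], 0L))

    ib <- initBlock(weights, bnState, "enc3", 3L, e[2], e[3])
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("enc3", 3L, e[2], e[3]))

    if (hasMFEB) {
      for (stage in 1:2) {
        cin <- if (stage == 1) e[3] else mp
        for (k in 1:3) {
          n <- 2L * k - 1L  # kernel sizes 1, 3, 5
          nm <- sprintf("mfeb%d.k%d", stage, n)
          ib <- initBlock(weights, bnState, nm, n, cin, mp)
          weights <- ib$weights; bnState <- ib$bnState
          add(blockLayers(nm, n, cin, mp))
        }
        add(layerRow(sprintf("mfeb%d.sum", stage), "sum", 0L, 1L, mp, mp, 0L))
      }
    }

    ib <- initBlock(weights, bnState, "bott", 3L, btIn, bt)
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("bott", 3L, btIn, bt))

    weights[["dec1.up.W"]] <- heConv(2L, bt, dc[1])
    weights[["dec1.up.b"]] <- numeric(dc[1])
    add(layerRow("dec1.up", "tconv", 2L, 2L, bt, dc[1],
      convParams(2L, bt, dc[1])))
    add(layerRow("dec1.merge", "concat", 0L, 1L, dc[1] + e[2], dc[1] + e[2],
      0L))
    ib <- initBlock(weights, bnState, "dec1", 3L, dc[1] + e[2], dc[1])
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("dec1", 3L, dc[1] + e[2], dc[1]))

    if (hasReverse) {
      weights[["rev1.W"]] <- heConv(1L, dc[1], e[1])
      weights[["rev1.b"]] <- numeric(e[1])
      add(layerRow("rev1.proj", "conv", 1L, 1L, dc[1], e[1],
        convParams(1L, dc[1], e[1])))
      add(layerRow("rev1.remap", "reverse_skip", 0L, 1L, e[1], e[1], 0L))
    }

    weights[["dec2.up.W"]] <- heConv(2L, dc[1], dc[2])
    weights[["dec2.up.b"]] <- numeric(dc[2])
    add(layerRow("dec2.up", "tconv", 2L, 2L, dc[1], dc[2],
      convParams(2L, dc[1], dc[2])))
    add(layerRow("dec2.merge", "concat", 0L, 1L, dc[2] + e[1], dc[2] + e[1],
      0L))
    ib <- initBlock(weights, bnState, "dec2", 3L, dc[2] + e[1], dc[2])
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("dec2", 3L, dc[2] + e[1], dc[2]))

    ib <- initBlock(weights, bnState, "dec3", 3L, dc[2], dc[3])
    weights <- ib$weights; bnState <- ib$bnState
    add(blockLayers("dec3", 3L, dc[2], dc[3]))

    weights[["head.W"]] <- heConv(1L, dc[3], nc)
    weights[["head.b"]] <- numeric(nc)
    add(layerRow("head.conv", "conv", 1L, 1L, dc[3], nc,
      convParams(1L, dc[3], nc)))
    add(layerRow("head.softmax", "softmax", 0L, 1L, nc, nc, 0L))
  })

  layers <- do.call(rbind, rows)
  total <- sum(layers$params)
  if (enforceBudget && total > PARAM_BUDGET) {
    tbl <- paste(utils::capture.output(print(layers)), collapse = "\n")
    stop("parameter budget exceeded: ", total, " > ", PARAM_BUDGET,
      " trainable parameters\n", tbl, call. = FALSE)
  }
  new("LMBiSNet", plan = plan, variant = variant, layers = layers,
    weights = weights, bnState = bnState, inputChannels = 3L)
}

#' Build a named ablation variant
#'
#' The ablation axes of the architecture study: `"lightweight_baseline"`
#' (single-path lightweight encoder-decoder, no multipath block, no reverse
#' skips), `"lbl_mfeb"` (adds the multipath feature-extraction block) and
#' `"full"` (adds the bidirectional skips). Their parameter counts increase
#' strictly in that order. `"baseline_unet"` is the heavy single-path
#' reference network (widths scaled 8x; exempt from the lightweight budget).
#'
#' @param name variant name.
#' @param plan the [ChannelPlan-class] for the lightweight variants.
#' @param seed integer weight-initialisation seed.
#' @return an [LMBiSNet-class].
#' @export
buildAblationVariant <- function(name, plan = channelPlan(), seed = 1L) {
  name <- match.arg(name,
    c("baseline_unet", "lightweight_baseline", "lbl_mfeb", "full"))
  if (name == "baseline_unet") {
    heavy <- channelPlan(
      stemChannels = plan@stemChannels * 8L,
      encoderChannels = plan@encoderChannels * 8L,
      multipathChannels = plan@multipathChannels * 8L,
      bottleneckChannels = plan@bottleneckChannels * 8L,
      decoderChannels = plan@decoderChannels * 8L,
      numClasses = plan@numClasses)
    buildNetwork(heavy, variant = "baseline_unet", seed = seed,
      enforceBudget = FALSE)
  } else {
    buildNetwork(plan, variant = name, seed = seed)
  }
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "LMBiSNet", function(object) {
  as.integer(sum(object@layers$params))
})

#' @rdname accessors
#' @export
setMethod("layerTable", "LMBiSNet", function(object) object@layers)

#' @rdname accessors
#' @export
setMethod("networkVariant", "LMBiSNet", function(object) object@variant)

setMethod("show", "LMBiSNet", function(object) {
  cat("LMBiSNet (variant '", object@variant, "')\n", sep = "")
  cat("  layers: ", nrow(object@layers),
    " (", sum(object@layers$kind == "maxpool"), " max-pool, ",
    sum(object@layers$kind == "tconv"), " transpose-conv)\n", sep = "")
  cat("  trainable parameters: ", countParameters(object),
    " (budget ", PARAM_BUDGET, ")\n", sep = "")
})

#' Export the per-layer parameter table
#'
#' @param net an [LMBiSNet-class].
#' @param path CSV destination.
#' @return the path, invisibly.
#' @export
writeParameterTable <- function(net, path) {
  utils::write.csv(layerTable(net), path, row.names = FALSE)
  invisible(path)
}

# ---- forward / backward ---------------------------------------------------

runBlock <- function(env, name, x, training) {
  w <- env$weights
  cv <- convForward(x, w[[paste0(name, ".W")]], w[[paste0(name, ".b")]])
  rl <- reluForward(cv$y)
  # running statistics: cumulative average for the first updates, then an
  # exponential moving average (momentum 0.9), so inference-mode behaviour
  # tracks training without a long warm-up bias
  cnt <- env$bnState[[paste0(name, ".n")]]
  if (is.null(cnt)) cnt <- 0L
  bn <- bnForward(rl$y, w[[paste0(name, ".gamma")]],
    w[[paste0(name, ".beta")]],
    env$bnState[[paste0(name, ".mean")]],
    env$bnState[[paste0(name, ".var")]], training,
    momentum = min(cnt / (cnt + 1), 0.9))
  if (training) {
    env$bnState[[paste0(name, ".mean")]] <- bn$runMean
    env$bnState[[paste0(name, ".var")]] <- bn$runVar
    env$bnState[[paste0(name, ".n")]] <- cnt + 1L
  }
  env$cache[[name]] <- list(conv = cv$cache, relu = rl$cache, bn = bn$cache)
  bn$y
}

backBlock <- function(env, name, dY, needInputGrad = TRUE) {
  cc <- env$cache[[name]]
  bb <- bnBackward(dY, cc$bn)
  env$grads[[paste0(name, ".gamma")]] <- bb$dgamma
  env$grads[[paste0(name, ".beta")]] <- bb$dbeta
  dr <- reluBackward(bb$dX, cc$relu)
  cb <- convBackward(dr, cc$conv, needInputGrad)
  env$grads[[paste0(name, ".W")]] <- cb$dW
  env$grads[[paste0(name, ".b")]] <- cb$db
  cb$dX
}

mfebStage <- function(env, stage, x, training) {
  out <- NULL
  for (n in c(1L, 3L, 5L)) {
    y <- runBlock(env, sprintf("mfeb%d.k%d", stage, n), x, training)
    out <- if (is.null(out)) y else out + y
  }
  out
}

mfebStageBack <- function(env, stage, dY) {
  dX <- NULL
  for (n in c(1L, 3L, 5L)) {
    d <- backBlock(env, sprintf("mfeb%d.k%d", stage, n), dY)
    dX <- if (is.null(dX)) d else dX + d
  }
  dX
}

# Shared forward pass. Returns logits plus (when keepCache) everything the
# backward pass needs. `env` accumulates BN running-statistic updates.
forwardPass <- function(net, x, training = FALSE, keepCache = training) {
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("input spatial dimensions must be divisible by 4; got ",
      d[1], " x ", d[2], call. = FALSE)
  if (d[4] != net@inputChannels)
    stop("expected ", net@inputChannels, "-channel input, got ", d[4],
      call. = FALSE)
  hasMFEB <- net@variant %in% c("full", "lbl_mfeb")
  hasReverse <- net@variant == "full"
  env <- new.env(parent = emptyenv())
  env$weights <- net@weights
  env$bnState <- net@bnState
  env$cache <- list()

  cv <- convForward(x, net@weights[["stem.W"]], net@weights[["stem.b"]])
  env$cache[["stem"]] <- cv$cache
  s <- cv$y
  e1 <- runBlock(env, "enc1", s, training)
  pl1 <- maxpoolForward(e1)
  e2 <- runBlock(env, "enc2", pl1$y, training)
  pl2 <- maxpoolForward(e2)
  e3 <- runBlock(env, "enc3", pl2$y, training)
  mpOut <- if (hasMFEB) {
    m1 <- mfebStage(env, 1L, e3, training)
    mfebStage(env, 2L, m1, training)
  } else e3
  bt <- runBlock(env, "bott", mpOut, training)

  tc1 <- tconvForward(bt, net@weights[["dec1.up.W"]],
    net@weights[["dec1.up.b"]])
  c1 <- concatChannels(tc1$y, e2)
  d1 <- runBlock(env, "dec1", c1, training)

  e1r <- e1
  if (hasReverse) {
    pr <- convForward(d1, net@weights[["rev1.W"]], net@weights[["rev1.b"]])
    env$cache[["rev1"]] <- pr$cache
    e1r <- e1 + nnUpsample2(pr$y)
  }

  tc2 <- tconvForward(d1, net@weights[["dec2.up.W"]],
    net@weights[["dec2.up.b"]])
  c2 <- concatChannels(tc2$y, e1r)
  d2 <- runBlock(env, "dec2", c2, training)
  d3 <- runBlock(env, "dec3", d2, training)
  hv <- convForward(d3, net@weights[["head.W"]], net@weights[["head.b"]])
  env$cache[["head"]] <- hv$cache

  out <- list(logits = hv$y, bnState = env$bnState)
  if (keepCache) {
    env$cache[["pool1"]] <- pl1$cache
    env$cache[["pool2"]] <- pl2$cache
    env$cache[["tconv1"]] <- tc1$cache
    env$cache[["tconv2"]] <- tc2$cache
    out$env <- env
    out$dims <- list(d1c = dim(tc1$y)[4], e2c = dim(e2)[4],
      d2c = dim(tc2$y)[4], e1c = dim(e1)[4])
  }
  out
}

# Backward pass from the loss gradient w.r.t. logits; returns gradients
# named like the weights.
backwardPass <- function(net, fw, dLogits) {
  env <- fw$env
  env$grads <- list()
  hasMFEB <- net@variant %in% c("full", "lbl_mfeb")
  hasReverse <- net@variant == "full"

  cb <- convBackward(dLogits, env$cache[["head"]])
  env$grads[["head.W"]] <- cb$dW; env$grads[["head.b"]] <- cb$db
  dd3 <- cb$dX
  dd2 <- backBlock(env, "dec3", dd3)
  dc2 <- backBlock(env, "dec2", dd2)
  sp2 <- splitChannels(dc2, fw$dims$d2c)
  du2 <- sp2$a; de1r <- sp2$b

  tb2 <- tconvBackward(du2, env$cache[["tconv2"]])
  env$grads[["dec2.up.W"]] <- tb2$dW; env$grads[["dec2.up.b"]] <- tb2$db
  dd1 <- tb2$dX

  de1 <- de1r  # identity branch of the additive remap
  if (hasReverse) {
    dproj <- nnUpsample2Backward(de1r)
    rb <- convBackward(dproj, env$cache[["rev1"]])
    env$grads[["rev1.W"]] <- rb$dW; env$grads[["rev1.b"]] <- rb$db
    dd1 <- dd1 + rb$dX
  }

  dc1 <- backBlock(env, "dec1", dd1)
  sp1 <- splitChannels(dc1, fw$dims$d1c)
  du1 <- sp1$a; de2a <- sp1$b

  tb1 <- tconvBackward(du1, env$cache[["tconv1"]])
  env$grads[["dec1.up.W"]] <- tb1$dW; env$grads[["dec1.up.b"]] <- tb1$db
  dbt <- tb1$dX

  dmp <- backBlock(env, "bott", dbt)
  de3 <- if (hasMFEB) {
    dm1 <- mfebStageBack(env, 2L, dmp)
    mfebStageBack(env, 1L, dm1)
  } else dmp

  dp2 <- backBlock(env, "enc3", de3)
  de2b <- maxpoolBackward(dp2, env$cache[["pool2"]])
  dp1 <- backBlock(env, "enc2", de2a + de2b)
  de1b <- maxpoolBackward(dp1, env$cache[["pool1"]])
  ds <- backBlock(env, "enc1", de1 + de1b)
  sb <- convBackward(ds, env$cache[["stem"]], needInputGrad = FALSE)
  env$grads[["stem.W"]] <- sb$dW; env$grads[["stem.b"]] <- sb$db
  env$grads
}

#' Run the network forward
#'
#' @param net an [LMBiSNet-class].
#' @param image an `H x W x 3` array (one image) or `H x W x 3 x N` batch,
#'   sides divisible by 4, values in any real range (typically `[0, 1]`).
#' @param training logical; `TRUE` uses batch statistics in the
#'   batch-normalisation layers (used internally by [trainNetwork()]),
#'   `FALSE` (default) the running statistics.
#' @return per-pixel class probabilities, `H x W x numClasses` for a single
#'   image or `H x W x numClasses x N` for a batch; every pixel's
#'   probabilities sum to 1.
#' @export
networkForward <- function(net, image, training = FALSE) {
  single <- length(dim(image)) == 3L
  fw <- forwardPass(net, toInternal(image), training = training,
    keepCache = FALSE)
  fromInternal(softmaxChannels(fw$logits), single)
}

#' Run the multipath feature-extraction block alone
#'
#' Executes one two-stage multipath block on a feature grid: each stage sends
#' its input through three parallel paths with kernel sizes `n = 2k - 1`
#' (1, 3 and 5), each path conv -> ReLU -> BN, and sums the three outputs
#' elementwise; the second stage consumes the first stage's sum. Exposed
#' separately so the path-sum decomposition is directly testable.
#'
#' @param x feature array `H x W x C` or `H x W x C x N`.
#' @param net a built [LMBiSNet-class] containing a multipath block (variant
#'   `"full"` or `"lbl_mfeb"`).
#' @param training logical, as in [networkForward()].
#' @return feature array of the same spatial size with
#'   `multipathChannels(plan)` channels.
#' @export
multipathForward <- function(x, net, training = FALSE) {
  if (!net@variant %in% c("full", "lbl_mfeb"))
    stop("variant '", net@variant, "' has no multipath block", call. = FALSE)
  single <- length(dim(x)) == 3L
  x <- toInternal(x)
  if (dim(x)[4] != net@plan@encoderChannels[3])
    stop("multipath block expects ", net@plan@encoderChannels[3],
      " input channels, got ", dim(x)[4], call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$weights <- net@weights
  env$bnState <- net@bnState
  env$cache <- list()
  y <- mfebStage(env, 2L, mfebStage(env, 1L, x, training), training)
  fromInternal(y, single)
}

#' Remap decoder features onto stored encoder features (reverse skip)
#'
#' Projects decoder features through a 1x1 convolution to the encoder
#' stage's channel width, upsamples them (nearest-neighbour) across the
#' scale gap, and adds them elementwise to the encoder features. With zero
#' projection weights the encoder features pass through unchanged; the
#' refined features feed only later-executing decoder merges, so the graph
#' stays acyclic.
#'
#' @param decoderFeatures array `H x W x C_dec (x N)` from the decoder stage.
#' @param encoderFeatures array `(s*H) x (s*W) x C_enc (x N)` stored encoder
#'   features, `s` a power of 2.
#' @param W,b projection weights: `1 x 1 x C_dec x C_enc` array and length
#'   `C_enc` bias.
#' @return refined encoder features, same shape as `encoderFeatures`.
#' @export
remapReverseSkip <- function(decoderFeatures, encoderFeatures, W, b) {
  single <- length(dim(decoderFeatures)) == 3L
  decoderFeatures <- toInternal(decoderFeatures)
  encoderFeatures <- toInternal(encoderFeatures)
  dd <- dim(decoderFeatures); de <- dim(encoderFeatures)
  if (de[1] %% dd[1] != 0L || de[2] %% dd[2] != 0L ||
      de[1] / dd[1] != de[2] / dd[2])
    stop("encoder/decoder spatial shapes are not related by an integer ",
      "scale factor", call. = FALSE)
  if (dim(W)[3] != dd[4] || dim(W)[4] != de[4])
    stop("projection weights are ", dim(W)[3], "->", dim(W)[4],
      " but features are ", dd[4], "->", de[4], call. = FALSE)
  y <- convForward(decoderFeatures, W, b)$y
  while (dim(y)[1] < de[1]) y <- nnUpsample2(y)
  fromInternal(encoderFeatures + y, single)
}
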