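#' Soft dice loss
#'
#' `1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)` with smoothing
#' `eps = 1` by default. On binary inputs this is one minus the dice
#' coefficient (equivalently one minus the F1 score) up to the smoothing
#' term; it is differentiable in the predicted probabilities and bounded in
#' `[0, 1]`.
#'
#' @param pred per-pixel vessel probabilities (any numeric array/matrix).
#' @param target binary mask of the same shape.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar loss in `[0, 1]`.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2)
#' diceLoss(m, m, smooth = 0)  # 0: perfect overlap
#' @export
diceLoss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target shapes differ", call. = FALSE)
  assertBinary(target, "target")
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  1 - num / den
}

# gradient of diceLoss w.r.t. pred
diceLossGrad <- function(pred, target, smooth = 1) {
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  -(2 * target * den - num) / den^2
}

#' One step of the reduce-on-plateau learning-rate schedule
#'
#' Tracks the best monitored validation dice; an epoch that fails to improve
#' it increments the stale counter, and once `patience` (7) consecutive
#' stale epochs accumulate the learning rate is halved (`factor` 0.5, floor
#' `lrFloor`) and the counter resets.
#'
#' @param state list with elements `lr`, `best` (best metric so far; use
#'   `-Inf` initially) and `stale` (consecutive epochs without improvement).
#' @param epochMetric this epoch's validation dice.
#' @param patience stale epochs tolerated before the cut.
#' @param factor multiplicative learning-rate factor.
#' @param lrFloor lower bound on the learning rate.
#' @return the updated state list.
#' @examples
#' st <- list(lr = 0.001, best = 0.5, stale = 0)
#' for (i in 1:7) st <- lrScheduleStep(st, 0.5)
#' st$lr  # 5e-04
#' @export
lrScheduleStep <- function(state, epochMetric, patience = 7L, factor = 0.5,
                           lrFloor = 1e-6) {
  stopifnot(state$lr > 0)
  if (epochMetric > state$best) {
    state$best <- epochMetric
    state$stale <- 0L
  } else {
    state$stale <- state$stale + 1L
    if (state$stale >= patience) {
      state$lr <- max(state$lr * factor, lrFloor)
      state$stale <- 0L
    }
  }
  state
}

# ---- Adam -----------------------------------------------------------------

adamInit <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
    v = lapply(weights, function(w) w * 0), t = 0L)
}

adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

# ---- batching -------------------------------------------------------------

# batches are assembled in the engine's internal (H, W, N, C) layout
stackBatch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]@image)
  x <- array(0, c(d[1], d[2], length(idx), 3L))
  g <- array(0, c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    s <- samples[[idx[j]]]
    if (!identical(dim(s@image), d))
      stop("all samples in a batch must share dimensions", call. = FALSE)
    x[, , j, ] <- s@image
    g[, , j] <- s@vesselMask
  }
  list(x = x, g = g)
}

# loss + gradient w.r.t. logits for a 2+-class softmax head with dice loss
# on the vessel class (channel 2). Internal (H, W, N, C) layout.
diceOnLogits <- function(logits, target, smooth = 1) {
  prob <- softmaxChannels(logits)
  nc <- dim(prob)[4]
  p <- prob[, , , 2L, drop = FALSE]
  dim(p) <- dim(target)
  loss <- diceLoss(p, target, smooth)
  dp <- diceLossGrad(p, target, smooth)
  dlog <- prob * 0
  for (j in seq_len(nc)) {
    pj <- prob[, , , j, drop = FALSE]
    dim(pj) <- dim(target)
    ind <- as.numeric(j == 2L)
    dlog[, , , j] <- dp * p * (ind - pj)
  }
  list(loss = loss, dLogits = dlog, prob = prob)
}

# mean soft dice (1 - loss, smooth 1) of a network over samples,
# inference mode
meanValidationDice <- function(net, samples) {
  mean(vapply(samples, function(s) {
    prob <- networkForward(net, s@image)
    1 - diceLoss(prob[, , 2L], s@vesselMask)
  }, numeric(1)))
}

#' Train the network
#'
#' Dice-loss training with Adam (initial learning rate from the config,
#' default 0.001), a ceiling of `maxEpochs` (50), halving of the learning
#' rate after `plateauPatience` (7) consecutive epochs without improvement
#' of the validation dice, and early stopping after `earlyStopPatience`
#' stale epochs. The weights of the best-validation epoch are returned.
#' Everything stochastic (sample order) is driven by `config@seed`.
#'
#' @param net a built [LMBiSNet-class].
#' @param trainSamples,valSamples nonempty lists of [FundusSample-class],
#'   all of one spatial size with sides divisible by 4.
#' @param config a [TrainingConfig-class].
#' @param verbose print one line per epoch.
#' @param stopValDice optional convergence target: stop as soon as the
#'   validation dice reaches this value (used by overfitting smoke tests;
#'   `NULL` trains to schedule).
#' @return list with `net` (trained, best-epoch weights and BN statistics),
#'   `history` (data.frame: epoch, loss, valDice, lr) and `bestEpoch`.
#' @export
trainNetwork <- function(net, trainSamples, valSamples,
                         config = trainingConfig(), verbose = FALSE,
                         stopValDice = NULL) {
  stopifnot(is(net, "LMBiSNet"), is(config, "TrainingConfig"))
  validObject(config)
  if (length(trainSamples) == 0L || length(valSamples) == 0L)
    stop("train and validation sets must be nonempty", call. = FALSE)

  weights <- net@weights
  opt <- adamInit(weights)
  sched <- list(lr = config@initialLr, best = -Inf, stale = 0L)
  bestVal <- -Inf; bestWeights <- weights; bestBn <- net@bnState
  bestEpoch <- 0L; staleTotal <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(),
    valDice = numeric(), lr = numeric())

  withSeed(config@seed, {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(length(trainSamples))
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      epochLoss <- 0
      for (b in batches) {
        bt <- stackBatch(trainSamples, b)
        net@weights <- weights
        fw <- forwardPass(net, bt$x, training = TRUE, keepCache = TRUE)
        net@bnState <- fw$bnState
        dl <- diceOnLogits(fw$logits, bt$g)
        if (!is.finite(dl$loss))
          stop("non-finite training loss at epoch ", epoch,
            "; check input scaling and learning rate", call. = FALSE)
        grads <- backwardPass(net, fw, dl$dLogits)
        upd <- adamStep(weights, grads, opt, sched$lr)
        weights <- upd$weights; opt <- upd$state
        epochLoss <- epochLoss + dl$loss * length(b)
      }
      epochLoss <- epochLoss / length(trainSamples)
      net@weights <- weights
      valDice <- meanValidationDice(net, valSamples)
      hist[nrow(hist) + 1L, ] <- list(epoch, epochLoss, valDice, sched$lr)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %g",
          epoch, epochLoss, valDice, sched$lr))
      if (valDice > bestVal) {
        bestVal <- valDice; bestWeights <- weights
        bestBn <- net@bnState; bestEpoch <- epoch
        staleTotal <- 0L
      } else {
        staleTotal <- staleTotal + 1L
      }
      sched <- lrScheduleStep(sched, valDice,
        patience = config@plateauPatience, factor = config@lrFactor)
      if (staleTotal >= config@earlyStopPatience) break
      if (!is.null(stopValDice) && valDice >= stopValDice) break
    }
  })
  net@weights <- bestWeights
  net@bnState <- bestBn
  list(net = net, history = hist, bestEpoch = bestEpoch)
}
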