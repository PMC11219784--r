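#' Pixelwise confusion counts
#'
#' Tallies TP/TN/FP/FN between a predicted and a ground-truth binary mask,
#' restricted to the FOV when a FOV mask is supplied (the standard
#' convention for fundus benchmarks, where pixels outside the circular
#' imaged region are uninformative).
#'
#' @param predMask,gtMask binary matrices of one shape.
#' @param fov optional binary FOV matrix; `NULL` evaluates the full frame.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(predMask, gtMask, fov = NULL) {
  if (!identical(dim(predMask), dim(gtMask)))
    stop("prediction and ground-truth shapes differ", call. = FALSE)
  assertBinary(predMask, "prediction")
  assertBinary(gtMask, "ground truth")
  if (!is.null(fov)) {
    if (!identical(dim(fov), dim(gtMask)))
      stop("FOV mask shape differs", call. = FALSE)
    assertBinary(fov, "FOV mask")
    keep <- fov == 1
    predMask <- predMask[keep]; gtMask <- gtMask[keep]
  }
  new("ConfusionCounts",
    tp = sum(predMask == 1 & gtMask == 1),
    tn = sum(predMask == 0 & gtMask == 0),
    fp = sum(predMask == 1 & gtMask == 0),
    fn = sum(predMask == 0 & gtMask == 1))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP", object@tp, " TN", object@tn,
    " FP", object@fp, " FN", object@fn, "\n")
})

safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Segmentation metrics from confusion counts
#'
#' The five standard retinal-vessel metrics, each a fraction in `[0, 1]`:
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, accuracy
#' `(TP + TN) / total`, F1 `2 TP / (2 TP + FP + FN)` (the dice coefficient
#' of the two masks), and the closed-form AUC
#' `1 - (FPR + FNR) / 2`, which is algebraically identical to
#' `(Se + Sp) / 2` (balanced accuracy at the fixed operating point — not a
#' ROC sweep; see [rocAuc()] for the conventional threshold-swept AUC).
#' A metric whose denominator is zero is undefined and reported as `NA`,
#' never as 0.
#'
#' @param object a [ConfusionCounts-class].
#' @return fraction in `[0, 1]`, or `NA` when undefined.
#' @name metrics
#' @examples
#' cc <- new("ConfusionCounts", tp = 8, fn = 2, tn = 9, fp = 1)
#' sensitivity(cc)    # 0.8
#' specificity(cc)    # 0.9
#' aucClosedForm(cc)  # 0.85 = (Se + Sp) / 2
NULL

#' @rdname metrics
#' @export
setMethod("sensitivity", "ConfusionCounts", function(object)
  safeRatio(object@tp, object@tp + object@fn))

#' @rdname metrics
#' @export
setMethod("specificity", "ConfusionCounts", function(object)
  safeRatio(object@tn, object@tn + object@fp))

#' @rdname metrics
#' @export
setMethod("accuracy", "ConfusionCounts", function(object)
  safeRatio(object@tp + object@tn,
    object@tp + object@tn + object@fp + object@fn))

#' @rdname metrics
#' @export
setMethod("f1Score", "ConfusionCounts", function(object)
  safeRatio(2 * object@tp, 2 * object@tp + object@fp + object@fn))

#' @rdname metrics
#' @export
setMethod("aucClosedForm", "ConfusionCounts", function(object) {
  if (object@fp + object@tn == 0 || object@fn + object@tp == 0)
    return(NA_real_)
  1 - 0.5 * (object@fp / (object@fp + object@tn) +
    object@fn / (object@fn + object@tp))
})

metricsVector <- function(cc) {
  c(Se = sensitivity(cc), Sp = specificity(cc), Acc = accuracy(cc),
    F1 = f1Score(cc), AUC = aucClosedForm(cc))
}

#' Threshold-swept ROC AUC
#'
#' The conventional trapezoidal area under the ROC curve of a probability
#' map against a binary ground truth, computed with \pkg{pROC}. This is the
#' secondary, threshold-free counterpart of [aucClosedForm()].
#'
#' @param probMap per-pixel vessel probabilities.
#' @param gtMask binary ground truth of the same shape.
#' @param fov optional binary FOV restriction.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(probMap, gtMask, fov = NULL) {
  keep <- if (is.null(fov)) rep(TRUE, length(gtMask)) else fov == 1
  as.numeric(pROC::auc(pROC::roc(
    response = as.vector(gtMask)[keep],
    predictor = as.vector(probMap)[keep],
    levels = c(0, 1), direction = "<", quiet = TRUE)))
}

#' Threshold a probability map
#'
#' Vessel where the vessel-class probability strictly exceeds the threshold;
#' ties go to background.
#'
#' @param probMap per-pixel vessel probabilities in `[0, 1]` (a matrix), or
#'   an `H x W x numClasses` probability array from [networkForward()], in
#'   which case channel 2 (vessel) is used.
#' @param threshold decision threshold, default 0.5.
#' @return binary mask matrix.
#' @export
binarizePrediction <- function(probMap, threshold = 0.5) {
  if (length(dim(probMap)) == 3L) probMap <- probMap[, , 2L]
  if (any(probMap < 0 | probMap > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  (probMap > threshold) * 1
}

#' Evaluate a set of predictions
#'
#' Computes the five metrics per image and their unweighted mean across
#' images (the dataset-level reporting convention). Undefined per-image
#' values (zero denominators) are excluded from the mean; how many were
#' excluded is recorded per metric. Set `pooled = TRUE` to additionally
#' aggregate all confusion counts into one pool before computing metrics.
#'
#' @param predictions list of binary masks.
#' @param groundTruths list of binary masks, aligned with `predictions`.
#' @param fovs optional list of FOV masks (or `NULL`s), aligned.
#' @param ids optional character ids for the per-image table.
#' @param pooled also compute pooled-pixel metrics (attribute `"pooled"`).
#' @return a [MetricsReport-class].
#' @export
evaluateDataset <- function(predictions, groundTruths, fovs = NULL,
                            ids = NULL, pooled = FALSE) {
  n <- length(predictions)
  if (n == 0L) stop("no predictions to evaluate", call. = FALSE)
  if (length(groundTruths) != n)
    stop("predictions and ground truths are misaligned (", n, " vs ",
      length(groundTruths), ")", call. = FALSE)
  if (!is.null(fovs) && length(fovs) != n)
    stop("predictions and FOV masks are misaligned", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(n))
  ccs <- lapply(seq_len(n), function(i)
    confusionCounts(predictions[[i]], groundTruths[[i]],
      if (is.null(fovs)) NULL else fovs[[i]]))
  per <- do.call(rbind, lapply(ccs, function(cc)
    as.data.frame(as.list(metricsVector(cc)))))
  per <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), per)
  mcols <- c("Se", "Sp", "Acc", "F1", "AUC")
  mu <- vapply(mcols, function(m) mean(per[[m]], na.rm = TRUE), numeric(1))
  und <- vapply(mcols, function(m) sum(is.na(per[[m]])), integer(1))
  if (any(und > 0))
    message("excluded ", sum(und), " undefined per-image metric value(s) ",
      "from the dataset mean")
  rep <- new("MetricsReport", perImage = per, mean = mu,
    undefinedCounts = und)
  if (pooled) {
    pool <- new("ConfusionCounts",
      tp = sum(vapply(ccs, function(c) c@tp, numeric(1))),
      tn = sum(vapply(ccs, function(c) c@tn, numeric(1))),
      fp = sum(vapply(ccs, function(c) c@fp, numeric(1))),
      fn = sum(vapply(ccs, function(c) c@fn, numeric(1))))
    attr(rep, "pooled") <- metricsVector(pool)
  }
  rep
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perImage), "image(s)\n")
  cat("  mean:",
    paste(sprintf("%s %.2f%%", names(object@mean), 100 * object@mean),
      collapse = "  "), "\n")
  if (any(object@undefinedCounts > 0))
    cat("  undefined values excluded:",
      sum(object@undefinedCounts), "\n")
})

#' Render an error overlay
#'
#' Colour-codes the comparison of a predicted and a ground-truth mask:
#' true positives green, false positives red, false negatives blue, true
#' negatives black.
#'
#' @param predMask,gtMask binary matrices of one shape.
#' @return `H x W x 3` RGB array.
#' @export
renderErrorOverlay <- function(predMask, gtMask) {
  if (!identical(dim(predMask), dim(gtMask)))
    stop("prediction and ground-truth shapes differ", call. = FALSE)
  assertBinary(predMask, "prediction")
  assertBinary(gtMask, "ground truth")
  out <- array(0, c(dim(predMask), 3L))
  out[, , 1][predMask == 1 & gtMask == 0] <- 1  # FP red
  out[, , 2][predMask == 1 & gtMask == 1] <- 1  # TP green
  out[, , 3][predMask == 0 & gtMask == 1] <- 1  # FN blue
  out
}
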