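#' Enumerate the transform descriptors of an augmentation policy
#'
#' The default policy expands each image 38-fold: 36 rotations in 10-degree
#' steps from 0 to 350 (identity included) followed by one unrotated variant
#' per contrast factor (0.9, 1.1). Order is deterministic: rotations
#' ascending, then contrast factors in listed order.
#'
#' @param policy an [AugmentationPolicy-class].
#' @return data.frame with columns `label`, `kind` ("rotation"/"contrast"),
#'   `angle` (degrees; NA for contrast) and `factor` (NA for rotations).
#' @examples
#' nrow(enumerateVariants(augmentationPolicy()))  # 38
#' @export
enumerateVariants <- function(policy) {
  stopifnot(is(policy, "AugmentationPolicy"))
  validObject(policy)
  angles <- (seq_len(policy@rotationCount) - 1L) * policy@rotationStep
  rot <- data.frame(
    label = sprintf("rot%03d", round(angles)),
    kind = "rotation", angle = angles, factor = NA_real_,
    stringsAsFactors = FALSE)
  con <- if (length(policy@contrastFactors)) data.frame(
    label = sprintf("con%g", policy@contrastFactors),
    kind = "contrast", angle = NA_real_, factor = policy@contrastFactors,
    stringsAsFactors = FALSE) else rot[0, ]
  rbind(rot, con)
}

#' @rdname accessors
#' @export
setMethod("variantCount", "AugmentationPolicy", function(object)
  object@rotationCount + length(object@contrastFactors))

setMethod("show", "AugmentationPolicy", function(object) {
  cat("AugmentationPolicy: ", object@rotationCount, " rotations at ",
    object@rotationStep, " deg + contrast factors {",
    paste(object@contrastFactors, collapse = ", "), "} -> ",
    variantCount(object), " variants per image\n", sep = "")
})

#' Rotate a sample about its center
#'
#' The image is rotated with bilinear interpolation (pixels swung off the
#' canvas are dropped; uncovered corners are filled with 0, matching the
#' black border of fundus photographs); vessel and FOV masks are rotated
#' jointly with nearest-neighbour sampling and re-binarised. Positive angles
#' rotate counterclockwise in display orientation.
#'
#' @param sample a [FundusSample-class].
#' @param angle degrees in `[0, 360)`.
#' @return the rotated [FundusSample-class].
#' @export
applyRotation <- function(sample, angle) {
  if (angle < 0 || angle >= 360)
    stop("rotation angle must lie in [0, 360); got ", angle, call. = FALSE)
  if (angle == 0) return(sample)
  img <- clamp01(rotateArray(sample@image, angle, "bilinear"))
  vm <- rotateMatrix(sample@vesselMask, angle, "nearest")
  fm <- if (is.null(sample@fovMask)) NULL else
    rotateMatrix(sample@fovMask, angle, "nearest")
  new("FundusSample", id = sample@id, image = img,
    vesselMask = rebinarize(vm, 0.5),
    fovMask = if (is.null(fm)) NULL else rebinarize(fm, 0.5),
    sourceResolution = sample@sourceResolution)
}

#' Scale the contrast of a sample
#'
#' Each channel is mapped to `mean + factor * (value - mean)` where the mean
#' is computed over the FOV (or the whole frame when no FOV mask is present),
#' then clipped to `[0, 1]`. Masks are unchanged. A factor below 1 compresses
#' intensities towards the mean (lower contrast), above 1 expands them.
#'
#' @param sample a [FundusSample-class].
#' @param factor positive contrast multiplier.
#' @return the contrast-adjusted [FundusSample-class].
#' @export
applyContrast <- function(sample, factor) {
  if (factor <= 0)
    stop("contrast factor must be positive; got ", factor, call. = FALSE)
  img <- sample@image
  sel <- if (is.null(sample@fovMask)) rep(TRUE, prod(dim(img)[1:2])) else
    sample@fovMask == 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    m <- mean(plane[sel])
    img[, , ch] <- clamp01(m + factor * (plane - m))
  }
  new("FundusSample", id = sample@id, image = img,
    vesselMask = sample@vesselMask, fovMask = sample@fovMask,
    sourceResolution = sample@sourceResolution)
}

applyVariant <- function(sample, descriptor) {
  out <- if (descriptor$kind == "rotation")
    applyRotation(sample, descriptor$angle)
  else
    applyContrast(sample, descriptor$factor)
  out@id <- paste(sample@id, descriptor$label, sep = "_")
  out
}

#' Expand a dataset with the augmentation policy
#'
#' Applies every transform descriptor of `policy` to every sample. The output
#' length is exactly `length(samples) * variantCount(policy)` (20 images
#' under the default policy give 760), and each output id encodes the source
#' id plus the transform label. The expansion is deterministic: there is no
#' hidden randomness.
#'
#' @param samples nonempty list of [FundusSample-class].
#' @param policy an [AugmentationPolicy-class].
#' @return list of augmented [FundusSample-class].
#' @export
augmentDataset <- function(samples, policy = augmentationPolicy()) {
  if (length(samples) == 0L)
    stop("cannot augment an empty sample list", call. = FALSE)
  variants <- enumerateVariants(policy)
  out <- vector("list", length(samples) * nrow(variants))
  k <- 0L
  for (s in samples) for (i in seq_len(nrow(variants))) {
    k <- k + 1L
    out[[k]] <- applyVariant(s, variants[i, ])
  }
  out
}
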