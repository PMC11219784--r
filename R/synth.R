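# Synthetic fundus-like data: circular FOV, smooth radial background,
# branching curvilinear vessel trees with width tapering into 1-px
# capillaries. Purely for exercising the pipeline end to end; it emulates
# geometry and contrast, not photographic realism or pathology.

#' Circular field-of-view mask
#'
#' @param side image side in pixels.
#' @param radiusFrac disc radius as a fraction of `side` (default 0.48,
#'   leaving the black corner border typical of fundus photographs).
#' @return binary matrix, 1 inside the disc.
#' @export
fovDisc <- function(side, radiusFrac = 0.48) {
  c0 <- (side + 1) / 2
  r <- matrix(seq_len(side), side, side) - c0
  c <- matrix(seq_len(side), side, side, byrow = TRUE) - c0
  ((r * r + c * c) <= (radiusFrac * side)^2) * 1
}

# stamp a disc of diameter `w` at each (y, x) center into mask
stampDiscs <- function(mask, ys, xs, ws, side) {
  for (rad in unique(pmax(ceiling(ws / 2), 1L))) {
    off <- expand.grid(dy = -rad:rad, dx = -rad:rad)
    off <- off[off$dy^2 + off$dx^2 <= rad^2 + 0.25, ]
    sel <- pmax(ceiling(ws / 2), 1L) == rad
    yy <- outer(ys[sel], off$dy, "+")
    xx <- outer(xs[sel], off$dx, "+")
    ok <- yy >= 1 & yy <= side & xx >= 1 & xx <= side
    mask[cbind(yy[ok], xx[ok])] <- 1
  }
  mask
}

#' Generate a synthetic vessel mask
#'
#' Grows `nTrees` branching trees by biased random walks: each tree starts
#' near the FOV margin heading inward; segments wander with angular jitter
#' and bifurcate with decreasing probability up to `branchDepth`; stroke
#' width tapers geometrically from `widthRange[2]` at the trunk to
#' `widthRange[1]` at the deepest branches (widths are specified at 512 px
#' and scale with `side`). The union of strokes is clipped to the FOV disc.
#' Fully deterministic given `config@seed`.
#'
#' @param config a [SynthConfig-class].
#' @return binary `side x side` matrix.
#' @export
generateVesselMask <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  side <- config@side
  mask <- matrix(0, side, side)
  if (config@nTrees == 0L) return(mask)
  scale <- side / 512
  wmin <- max(config@widthRange[1] * scale, 1)
  wmax <- max(config@widthRange[2] * scale, wmin)
  c0 <- (side + 1) / 2
  R <- 0.48 * side
  depthMax <- max(config@branchDepth, 1L)

  withSeed(config@seed, {
    ys <- numeric(); xs <- numeric(); ws <- numeric()
    for (t in seq_len(config@nTrees)) {
      a0 <- runif(1, 0, 2 * pi)
      # stack of segments: position, heading, depth
      stack <- list(list(
        y = c0 + 0.82 * R * sin(a0),
        x = c0 + 0.82 * R * cos(a0),
        th = a0 + pi + runif(1, -0.4, 0.4),  # head roughly inward
        depth = 0L))
      while (length(stack)) {
        seg <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        w <- wmax * (wmin / wmax)^(seg$depth / depthMax)
        nsteps <- round(runif(1, 0.10, 0.20) * side)
        y <- seg$y; x <- seg$x; th <- seg$th
        for (i in seq_len(nsteps)) {
          th <- th + rnorm(1, 0, 0.14)
          y <- y + 1.4 * sin(th); x <- x + 1.4 * cos(th)
          if ((y - c0)^2 + (x - c0)^2 > R * R) break
          ys[length(ys) + 1L] <- y
          xs[length(xs) + 1L] <- x
          ws[length(ws) + 1L] <- w
        }
        inside <- (y - c0)^2 + (x - c0)^2 <= R * R
        if (inside && seg$depth < depthMax && runif(1) < 0.75) {
          split <- runif(1, 0.25, 0.55)
          for (sgn in c(-1, 1))
            stack[[length(stack) + 1L]] <- list(y = y, x = x,
              th = th + sgn * split, depth = seg$depth + 1L)
        }
      }
    }
    if (length(ys))
      mask <- stampDiscs(mask, round(ys), round(xs), ws, side)
  })
  mask * fovDisc(side)
}

#' Render a fundus-like image from a vessel mask
#'
#' Background inside the FOV disc is a smooth radial gradient of a reddish
#' base colour (brightest at the center, as in real fundus photographs),
#' black outside. Vessel pixels are darkened by `vesselContrast`; Gaussian
#' noise of sd `noiseSd` is added inside the FOV and the result clipped to
#' `[0, 1]`.
#'
#' @param mask binary `side x side` vessel mask.
#' @param config a [SynthConfig-class]; `config@side` must match the mask.
#' @return `H x W x 3` RGB array.
#' @export
renderFundus <- function(mask, config) {
  stopifnot(is(config, "SynthConfig"))
  side <- config@side
  if (!identical(dim(mask), c(side, side)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
      " does not match config side ", side, call. = FALSE)
  fov <- fovDisc(side)
  c0 <- (side + 1) / 2
  r <- matrix(seq_len(side), side, side) - c0
  c <- matrix(seq_len(side), side, side, byrow = TRUE) - c0
  rr <- sqrt(r * r + c * c) / (0.48 * side)
  shade <- 1 - 0.35 * pmin(rr, 1)^2
  base <- c(0.72, 0.42, 0.22)  # reddish fundus tone
  img <- array(0, c(side, side, 3L))
  withSeed(config@seed + 7901L, {
    for (ch in 1:3) {
      plane <- base[ch] * shade
      plane[mask == 1] <- plane[mask == 1] * (1 - config@vesselContrast)
      if (config@noiseSd > 0)
        plane <- plane + rnorm(side * side, 0, config@noiseSd)
      img[, , ch] <- clamp01(plane) * fov
    }
  })
  img
}

#' Generate a synthetic dataset
#'
#' `n` samples with derived seeds `seed, seed + 1, ...` so the collection is
#' reproducible yet the samples differ.
#'
#' @param n number of samples, at least 1.
#' @param config a [SynthConfig-class]; per-sample seed is `config@seed + i - 1`.
#' @return list of [FundusSample-class] with image, vessel mask and FOV disc.
#' @export
makeSyntheticDataset <- function(n, config = synthConfig()) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg@seed <- config@seed + i - 1L
    mask <- generateVesselMask(cfg)
    fundusSample(
      id = sprintf("synth%03d", i),
      image = renderFundus(mask, cfg),
      vesselMask = mask,
      fovMask = fovDisc(cfg@side))
  })
}
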