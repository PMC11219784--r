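# Shared raster helpers. Pixel convention throughout: row-major, 0-based
# pixel centers at integer coordinates + 0.5 when mapped to continuous space
# ("center-aligned"); masks are {0,1} with 1 = foreground.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

isBinary <- function(m) all(m %in% c(0, 1))

assertBinary <- function(m, what = "mask") {
  if (!isBinary(m)) stop(what, " must be binary {0,1}", call. = FALSE)
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Source pixel-center coordinates (1-based, fractional) for resizing a length
# `nIn` axis to `nOut`, center-aligned: out pixel i covers the same relative
# span as in the source.
resizeCoords <- function(nIn, nOut) {
  (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
}

# Nearest-neighbour resize of a matrix.
nnResizeMatrix <- function(m, nrowOut, ncolOut) {
  ri <- pmin(pmax(floor(resizeCoords(nrow(m), nrowOut) - 0.5) + 1L, 1L), nrow(m))
  ci <- pmin(pmax(floor(resizeCoords(ncol(m), ncolOut) - 0.5) + 1L, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Bilinear resize of a matrix (one channel).
bilinearResizeMatrix <- function(m, nrowOut, ncolOut) {
  H <- nrow(m); W <- ncol(m)
  ry <- resizeCoords(H, nrowOut); cx <- resizeCoords(W, ncolOut)
  y0 <- pmin(pmax(floor(ry), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(cx), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(cx - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * ((1 - wy) %o% (1 - wx)) +
    m[y0, x1, drop = FALSE] * ((1 - wy) %o% wx)
  bot <- m[y1, x0, drop = FALSE] * (wy %o% (1 - wx)) +
    m[y1, x1, drop = FALSE] * (wy %o% wx)
  top + bot
}

# Resize a H x W x C array channel by channel.
bilinearResizeArray <- function(a, nrowOut, ncolOut) {
  out <- array(0, c(nrowOut, ncolOut, dim(a)[3]))
  for (ch in seq_len(dim(a)[3]))
    out[, , ch] <- bilinearResizeMatrix(a[, , ch], nrowOut, ncolOut)
  out
}

# Rotate one channel by `angle` degrees counterclockwise about the image
# center via inverse mapping. interp = "bilinear" (fill 0 outside the canvas)
# or "nearest". With nearest interpolation a 90-degree rotation of a square
# grid is an exact index permutation.
rotateMatrix <- function(m, angle, interp = c("bilinear", "nearest"),
                         fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cy
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation: output (r, c) samples source rotated by -angle.
  # Image rows grow downward, so a counterclockwise rotation in display
  # coordinates uses the clockwise matrix on (row, col).
  sr <- cos(th) * r - sin(th) * c + cy
  sc <- sin(th) * r + cos(th) * c + cx
  out <- matrix(fill, H, W)
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- m[cbind(ri[ok], ci[ok])]
  } else {
    y0 <- floor(sr); x0 <- floor(sc)
    wy <- sr - y0; wx <- sc - x0
    acc <- matrix(0, H, W); wsum <- matrix(0, H, W)
    for (dy in 0:1) for (dx in 0:1) {
      yy <- y0 + dy; xx <- x0 + dx
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      w <- (if (dy == 0) 1 - wy else wy) * (if (dx == 0) 1 - wx else wx)
      acc[ok] <- acc[ok] + w[ok] * m[cbind(yy[ok], xx[ok])]
      wsum[ok] <- wsum[ok] + w[ok]
    }
    inside <- wsum > 0
    out[inside] <- acc[inside]  # partial canvas overlap: fill contributes 0
  }
  out
}

rotateArray <- function(a, angle, interp = "bilinear") {
  out <- a
  for (ch in seq_len(dim(a)[3]))
    out[, , ch] <- rotateMatrix(a[, , ch], angle, interp)
  out
}

rebinarize <- function(m, threshold = 0.5) {
  (m > threshold) * 1
}
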