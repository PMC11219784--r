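# Minimal CNN engine. Internal tensor layout is (H, W, N, C) — channels
# last — so the (H*W*N) x C "pixel matrix" view used by the BLAS matmuls is
# a zero-copy reshape. Convolutions run as im2col + matmul; every primitive
# returns the cache its backward pass needs. Gradients are validated against
# finite differences in the test suite.

# ---- reshaping ------------------------------------------------------------

# (H, W, N, C) -> (H*W*N, C); zero-copy
toPixelMatrix <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

fromPixelMatrix <- function(m, H, W, N) {
  dim(m) <- c(H, W, N, ncol(m))
  m
}

# public (H, W, C[, N]) <-> internal (H, W, N, C)
toInternal <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  aperm(x, c(1, 2, 4, 3))
}

fromInternal <- function(x, single = FALSE) {
  y <- aperm(x, c(1, 2, 4, 3))
  if (single) dim(y) <- dim(y)[1:3]
  y
}

# weight array (k, k, Cin, Cout) -> (k^2*Cin, Cout) matching im2col layout
# (channel fastest within each kernel-offset block, dy before dx).
weightMatrix <- function(W) {
  d <- dim(W)
  m <- aperm(W, c(3, 1, 2, 4))
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  m
}

weightArrayFromMatrix <- function(m, k, Cin, Cout) {
  dim(m) <- c(Cin, k, k, Cout)
  aperm(m, c(2, 3, 1, 4))
}

# ---- convolution (same padding, stride 1) ---------------------------------

im2col <- function(x, k) {
  if (k == 1L) return(toPixelMatrix(x))
  im2col_cpp(x, k)
}

addBias <- function(Y, b) {
  Y + rep(b, each = nrow(Y))
}

convForward <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]
  Xcol <- im2col(x, k)
  Y <- addBias(Xcol %*% weightMatrix(W), b)
  list(y = fromPixelMatrix(Y, d[1], d[2], d[3]),
    cache = list(Xcol = Xcol, dims = d, k = k, W = W))
}

# kernel flipped in both spatial dims with in/out channels swapped: the
# input gradient of a same-padded stride-1 correlation is the correlation
# of the output gradient with this flipped kernel.
flipKernel <- function(W) {
  k <- dim(W)[1]
  aperm(W[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
}

convBackward <- function(dY, cache, needInputGrad = TRUE) {
  d <- cache$dims; k <- cache$k
  dYm <- toPixelMatrix(dY)
  dWm <- crossprod(cache$Xcol, dYm)
  dW <- weightArrayFromMatrix(dWm, k, d[4], dim(cache$W)[4])
  db <- colSums(dYm)
  dX <- NULL
  if (needInputGrad) {
    if (k == 1L) {
      dX <- fromPixelMatrix(tcrossprod(dYm, weightMatrix(cache$W)),
        d[1], d[2], d[3])
    } else {
      dYcol <- im2col_cpp(dY, k)
      dX <- fromPixelMatrix(dYcol %*% weightMatrix(flipKernel(cache$W)),
        d[1], d[2], d[3])
    }
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- ReLU -----------------------------------------------------------------

reluForward <- function(x) list(y = pmax(x, 0), cache = x > 0)
reluBackward <- function(dY, cache) dY * cache

# ---- batch normalisation --------------------------------------------------
# Per-channel over (H, W, N). Training mode uses batch statistics (biased
# variance) and reports updated running statistics (momentum 0.9); inference
# mode uses the running statistics. Epsilon 1e-5.

bnForward <- function(x, gamma, beta, runMean, runVar, training,
                      eps = 1e-5, momentum = 0.9) {
  d <- dim(x)
  xm <- toPixelMatrix(x)
  if (training) {
    m <- colMeans(xm)
    v <- pmax(colMeans(xm * xm) - m * m, 0)
    newMean <- momentum * runMean + (1 - momentum) * m
    newVar <- momentum * runVar + (1 - momentum) * v
  } else {
    m <- runMean; v <- runVar
    newMean <- runMean; newVar <- runVar
  }
  inv <- 1 / sqrt(v + eps)
  n <- nrow(xm)
  xhat <- (xm - rep(m, each = n)) * rep(inv, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = fromPixelMatrix(y, d[1], d[2], d[3]),
    cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d,
      training = training),
    runMean = newMean, runVar = newVar)
}

bnBackward <- function(dY, cache) {
  d <- cache$dims
  dYm <- toPixelMatrix(dY)
  n <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(cache$gamma, each = n)
  if (cache$training) {
    t1 <- dxhat - rep(colMeans(dxhat), each = n)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
    dXm <- (t1 - t2) * rep(cache$inv, each = n)
  } else {
    dXm <- dxhat * rep(cache$inv, each = n)
  }
  list(dX = fromPixelMatrix(dXm, d[1], d[2], d[3]),
    dgamma = dgamma, dbeta = dbeta)
}

# ---- 2x2 max pooling, stride 2 --------------------------------------------

maxpoolForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  s <- list(
    x[seq(1, H, 2), seq(1, W, 2), , , drop = FALSE],
    x[seq(2, H, 2), seq(1, W, 2), , , drop = FALSE],
    x[seq(1, H, 2), seq(2, W, 2), , , drop = FALSE],
    x[seq(2, H, 2), seq(2, W, 2), , , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # first maximal window position wins ties (deterministic)
  arg <- array(4L, dim(y))
  arg[s[[3]] == y] <- 3L
  arg[s[[2]] == y] <- 2L
  arg[s[[1]] == y] <- 1L
  list(y = y, cache = list(arg = arg, dims = d))
}

maxpoolBackward <- function(dY, cache) {
  d <- cache$dims
  dX <- array(0, d)
  rows <- list(seq(1, d[1], 2), seq(2, d[1], 2))
  cols <- list(seq(1, d[2], 2), seq(2, d[2], 2))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (o in 1:4) {
    m <- dY * (cache$arg == o)
    dX[rows[[sel[[o]][1]]], cols[[sel[[o]][2]]], , ] <- m
  }
  dX
}

# ---- 2x2 transpose convolution, stride 2 ----------------------------------
# Non-overlapping: each input pixel expands into a 2x2 output block.

tconvForward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]
  Cin <- dim(W)[3]; Cout <- dim(W)[4]
  xm <- toPixelMatrix(x)
  y <- array(0, c(2L * H, 2L * Wd, N, Cout))
  for (dy in 0:1) for (dx in 0:1) {
    Wm <- matrix(W[dy + 1L, dx + 1L, , ], Cin, Cout)
    Yo <- addBias(xm %*% Wm, b)
    y[seq(dy + 1L, 2L * H, 2), seq(dx + 1L, 2L * Wd, 2), , ] <-
      fromPixelMatrix(Yo, H, Wd, N)
  }
  list(y = y, cache = list(xm = xm, dims = d, W = W))
}

tconvBackward <- function(dY, cache) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; N <- d[3]
  W <- cache$W; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  dW <- array(0, dim(W)); db <- numeric(Cout)
  dXm <- matrix(0, nrow(cache$xm), ncol(cache$xm))
  for (dy in 0:1) for (dx in 0:1) {
    dYo <- dY[seq(dy + 1L, 2L * H, 2), seq(dx + 1L, 2L * Wd, 2), , ,
      drop = FALSE]
    dim(dYo) <- c(H * Wd * N, Cout)
    dW[dy + 1L, dx + 1L, , ] <- crossprod(cache$xm, dYo)
    db <- db + colSums(dYo)
    dXm <- dXm + tcrossprod(dYo, matrix(W[dy + 1L, dx + 1L, , ], Cin, Cout))
  }
  list(dX = fromPixelMatrix(dXm, H, Wd, N), dW = dW, db = db)
}

# ---- misc structural ops --------------------------------------------------

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

splitChannels <- function(d, c1) {
  list(a = d[, , , seq_len(c1), drop = FALSE],
    b = d[, , , -seq_len(c1), drop = FALSE])
}

nnUpsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

nnUpsample2Backward <- function(dY) {
  d <- dim(dY)
  dY[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dY[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    dY[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    dY[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
}

softmaxChannels <- function(logits) {
  d <- dim(logits)
  lm <- toPixelMatrix(logits)
  mx <- lm[, 1L]
  for (j in seq_len(ncol(lm))[-1L]) mx <- pmax(mx, lm[, j])
  e <- exp(lm - mx)
  fromPixelMatrix(e / rowSums(e), d[1], d[2], d[3])
}

# ---- initialisation -------------------------------------------------------

# He-uniform: variance 2/fan_in, matched to ReLU activations
heConv <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  array(runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout))
}
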