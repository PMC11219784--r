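test_that("the default network respects the parameter budget exactly", {
  net <- buildNetwork(channelPlan(), seed = 1)
  n <- countParameters(net)
  expect_lte(n, 172000L)
  # the layer-table accounting agrees with the engine's own weight store
  expect_equal(n, sum(vapply(net@weights, length, numeric(1))))

  # closed forms on single layers, read off the layer table
  lt <- layerTable(net)
  enc2conv <- lt[lt$name == "enc2.conv", ]
  expect_equal(enc2conv$params, 9 * 8 * 16 + 16)  # 1168
  enc2bn <- lt[lt$name == "enc2.bn", ]
  expect_equal(enc2bn$params, 2 * 16)             # 32

  # oversized plans are rejected at build time with the per-layer table
  expect_error(
    buildNetwork(channelPlan(stemChannels = 64L,
      encoderChannels = c(64L, 128L, 256L), multipathChannels = 256L,
      bottleneckChannels = 256L, decoderChannels = c(256L, 128L, 64L))),
    "budget exceeded")
})

test_that("the graph has the published structure", {
  lt <- layerTable(buildNetwork(channelPlan(), seed = 1))
  expect_equal(sum(lt$kind == "maxpool"), 2L)
  expect_equal(sum(grepl("^enc[123]\\.conv$", lt$name)), 3L)
  expect_equal(sum(grepl("^dec[123]\\.conv$", lt$name)), 3L)
  # two poolings pair with two strided upsamplings; D3 refines at full res
  expect_equal(sum(lt$kind == "tconv"), 2L)
  # multipath kernels are n = 2k - 1 for k = 1..3
  mf <- lt[grepl("^mfeb1\\..*\\.conv$", lt$name), ]
  expect_setequal(mf$kernel, c(1L, 3L, 5L))
  # the softmax head emits one channel per class
  expect_equal(lt$outChannels[lt$name == "head.conv"], 2L)
  # execution order is a topological order: the reverse skip consumes D1
  # and refines E1 before D2 runs
  expect_true(which(lt$name == "rev1.remap") > which(lt$name == "dec1.bn"))
  expect_true(which(lt$name == "rev1.remap") < which(lt$name == "dec2.conv"))
})

test_that("forward output is a probability map of the input shape", {
  net <- buildNetwork(tinyPlan(), seed = 2)
  set.seed(1)
  for (side in c(16L, 24L)) {
    x <- array(runif(side * side * 3), c(side, side, 3L))
    p <- networkForward(net, x)
    expect_equal(dim(p), c(side, side, 2L))
    expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
    expect_true(all(p >= 0))
  }
  # determinism: identical weights, identical output
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(networkForward(net, x), networkForward(net, x))
  expect_error(networkForward(net, array(0, c(18, 18, 3))), "divisible by 4")
})

test_that("a zero-weight network emits the uniform probability map", {
  net <- buildNetwork(tinyPlan(), seed = 3)
  net@weights <- lapply(net@weights, function(w) w * 0)
  p <- networkForward(net, array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(max(abs(p - 0.5)), 0, tolerance = 1e-12)
})

test_that("the multipath block equals the explicit sum of its three paths", {
  net <- buildNetwork(tinyPlan(), seed = 4)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))

  # independent oracle: run each path (conv -> ReLU -> BN in inference
  # mode) with the net's own weights, on unbatched matrix arithmetic
  pathOut <- function(stage, n, xin) {
    nm <- sprintf("mfeb%d.k%d", stage, n)
    w <- net@weights
    xi <- array(xin, c(dim(xin), 1L))
    xi <- aperm(xi, c(1, 2, 4, 3))
    cv <- lmbisnet:::convForward(xi, w[[paste0(nm, ".W")]],
      w[[paste0(nm, ".b")]])$y
    rl <- pmax(cv, 0)
    bn <- lmbisnet:::bnForward(rl, w[[paste0(nm, ".gamma")]],
      w[[paste0(nm, ".beta")]], net@bnState[[paste0(nm, ".mean")]],
      net@bnState[[paste0(nm, ".var")]], training = FALSE)$y
    aperm(bn, c(1, 2, 4, 3))[, , , 1]
  }
  s1 <- pathOut(1, 1, x) + pathOut(1, 3, x) + pathOut(1, 5, x)
  expected <- pathOut(2, 1, s1) + pathOut(2, 3, s1) + pathOut(2, 5, s1)
  got <- multipathForward(x, net)
  expect_equal(got, expected, tolerance = 1e-10)
  expect_equal(dim(got), c(8L, 8L, 4L))

  # zero weights propagate to a zero output (ReLU and inference BN at
  # zero statistics)
  z <- net
  z@weights <- lapply(z@weights, function(w) w * 0)
  expect_true(all(multipathForward(x, z) == 0))

  expect_error(multipathForward(array(0, c(8, 8, 7)), net), "channels")
  lw <- buildAblationVariant("lightweight_baseline", tinyPlan())
  expect_error(multipathForward(x, lw), "no multipath block")
})

test_that("a lone 1x1 path acts as the hand-computed per-pixel affine map", {
  net <- buildNetwork(tinyPlan(), seed = 5)
  w <- net@weights
  # silence the 3x3 and 5x5 paths of stage 1 and run stage 1 only by
  # making stage 2's 1x1 path an identity-free check: compare against
  # explicit matrix arithmetic of conv1x1 -> ReLU -> BN
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  W1 <- w[["mfeb1.k1.W"]]; b1 <- w[["mfeb1.k1.b"]]
  g1 <- w[["mfeb1.k1.gamma"]]; be1 <- w[["mfeb1.k1.beta"]]
  mu <- net@bnState[["mfeb1.k1.mean"]]; va <- net@bnState[["mfeb1.k1.var"]]
  xm <- matrix(x, 9, 4)                       # pixels x channels
  z <- pmax(xm %*% matrix(W1[1, 1, , ], 4, 4) +
    matrix(b1, 9, 4, byrow = TRUE), 0)
  zh <- (z - matrix(mu, 9, 4, byrow = TRUE)) /
    matrix(sqrt(va + 1e-5), 9, 4, byrow = TRUE)
  manual <- zh * matrix(g1, 9, 4, byrow = TRUE) +
    matrix(be1, 9, 4, byrow = TRUE)

  xi <- aperm(array(x, c(dim(x), 1L)), c(1, 2, 4, 3))
  cv <- lmbisnet:::convForward(xi, W1, b1)$y
  bn <- lmbisnet:::bnForward(pmax(cv, 0), g1, be1, mu, va, FALSE)$y
  expect_equal(matrix(bn, 9, 4), manual, tolerance = 1e-12)
})

test_that("the reverse skip remaps decoder features onto the encoder", {
  set.seed(11)
  enc <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  dec <- array(rnorm(4 * 4 * 3), c(4, 4, 3))

  # zero projection leaves the encoder features unchanged
  W0 <- array(0, c(1, 1, 3, 2))
  expect_equal(remapReverseSkip(dec, enc, W0, numeric(2)), enc)

  # identity projection on matched 1-channel shapes adds the features
  e1 <- array(rnorm(4 * 4), c(4, 4, 1))
  d1 <- array(rnorm(4 * 4), c(4, 4, 1))
  Wi <- array(1, c(1, 1, 1, 1))
  expect_equal(remapReverseSkip(d1, e1, Wi, 0), e1 + d1, tolerance = 1e-12)

  # across a 2x scale gap the output takes the encoder shape
  out <- remapReverseSkip(dec, enc, array(rnorm(6), c(1, 1, 3, 2)),
    numeric(2))
  expect_equal(dim(out), dim(enc))

  expect_error(remapReverseSkip(dec, array(0, c(8, 8, 2)),
    array(0, c(1, 1, 2, 2)), numeric(2)), "projection weights")
})

test_that("ablation variants nest by parameter count", {
  plans <- channelPlan()
  lw <- buildAblationVariant("lightweight_baseline", plans)
  mf <- buildAblationVariant("lbl_mfeb", plans)
  fl <- buildAblationVariant("full", plans)
  expect_lt(countParameters(lw), countParameters(mf))
  expect_lt(countParameters(mf), countParameters(fl))
  # the full variant is the default build
  expect_identical(layerTable(fl), layerTable(buildNetwork(plans)))
  # multipath nodes present only from lbl_mfeb on
  expect_false(any(grepl("mfeb", layerTable(lw)$name)))
  expect_true(any(grepl("mfeb", layerTable(mf)$name)))
  expect_false(any(grepl("rev1", layerTable(mf)$name)))
  expect_true(any(grepl("rev1", layerTable(fl)$name)))
  # the heavy reference baseline dwarfs the lightweight budget
  expect_gt(countParameters(buildAblationVariant("baseline_unet", plans)),
    172000L)
  expect_error(buildAblationVariant("nonesuch"), "arg")
})

test_that("analytic gradients match finite differences", {
  net <- buildNetwork(tinyPlan(), seed = 3)
  set.seed(42)
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))  # internal (H, W, N, C)
  g <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2))
  lossAt <- function(w) {
    net@weights <- w
    fw <- lmbisnet:::forwardPass(net, x, training = TRUE, keepCache = FALSE)
    lmbisnet:::diceOnLogits(fw$logits, g)$loss
  }
  fw <- lmbisnet:::forwardPass(net, x, training = TRUE, keepCache = TRUE)
  dl <- lmbisnet:::diceOnLogits(fw$logits, g)
  grads <- lmbisnet:::backwardPass(net, fw, dl$dLogits)
  eps <- 1e-6
  for (nm in c("stem.W", "enc2.W", "enc1.gamma", "mfeb1.k5.W", "mfeb2.k1.b",
    "bott.beta", "dec1.up.W", "rev1.W", "dec2.W", "dec3.gamma", "head.b")) {
    i <- sample(length(grads[[nm]]), 1L)
    w2 <- net@weights; w2[[nm]][i] <- w2[[nm]][i] + eps
    w3 <- net@weights; w3[[nm]][i] <- w3[[nm]][i] - eps
    num <- (lossAt(w2) - lossAt(w3)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-3,
      label = paste("gradient of", nm))
  }
})
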