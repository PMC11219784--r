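test_that("confusion counts match a brute-force per-pixel loop", {
  ones <- matrix(1, 4, 4)
  cc <- confusionCounts(ones, ones)
  expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), c(16, 0, 0, 0))

  cc2 <- confusionCounts(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_equal(cc2@fp, 4)

  set.seed(13)
  p <- matrix(rbinom(64, 1, 0.5), 8, 8)
  g <- matrix(rbinom(64, 1, 0.5), 8, 8)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (p[i, j] == 1 && g[i, j] == 1) tp <- tp + 1
    if (p[i, j] == 0 && g[i, j] == 0) tn <- tn + 1
    if (p[i, j] == 1 && g[i, j] == 0) fp <- fp + 1
    if (p[i, j] == 0 && g[i, j] == 1) fn <- fn + 1
  }
  cc3 <- confusionCounts(p, g)
  expect_equal(c(cc3@tp, cc3@tn, cc3@fp, cc3@fn), c(tp, tn, fp, fn))

  # FOV restriction drops everything outside the mask
  fov <- matrix(0, 8, 8); fov[1:4, ] <- 1
  cc4 <- confusionCounts(p, g, fov)
  expect_equal(cc4@tp + cc4@tn + cc4@fp + cc4@fn, 32)

  expect_error(confusionCounts(p, g[1:4, ]), "shapes differ")
  expect_error(confusionCounts(p * 0.5, g), "binary")
})

test_that("metrics evaluate their defining ratios and signal undefined", {
  cc <- function(tp, tn, fp, fn)
    new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)

  expect_equal(sensitivity(cc(1, 0, 0, 0)), 1)
  expect_equal(sensitivity(cc(3, 0, 0, 1)), 0.75)
  expect_equal(sensitivity(cc(0, 0, 0, 5)), 0)
  expect_true(is.na(sensitivity(cc(0, 9, 1, 0))))  # TP + FN = 0

  expect_equal(specificity(cc(0, 1, 0, 0)), 1)
  expect_equal(specificity(cc(0, 9, 1, 0)), 0.9)
  expect_equal(specificity(cc(0, 0, 2, 0)), 0)

  expect_equal(accuracy(cc(5, 5, 0, 0)), 1)
  expect_equal(accuracy(cc(2, 6, 1, 1)), 0.8)
  expect_equal(accuracy(cc(0, 0, 3, 3)), 0)

  expect_equal(f1Score(cc(4, 0, 0, 0)), 1)
  expect_equal(f1Score(cc(2, 0, 1, 1)), 2 / 3)
  expect_equal(f1Score(cc(0, 0, 1, 1)), 0)
  expect_true(is.na(f1Score(cc(0, 5, 0, 0))))

  expect_equal(aucClosedForm(cc(8, 9, 0, 0)), 1)
  expect_equal(aucClosedForm(cc(8, 9, 1, 2)), 0.85)  # (0.8 + 0.9) / 2
  # all-background prediction on balanced pixels: FPR 0, FNR 1 -> 0.5
  expect_equal(aucClosedForm(cc(0, 8, 0, 8)), 0.5)
  expect_true(is.na(aucClosedForm(cc(3, 0, 0, 1))))
})

test_that("closed-form AUC is exactly the mean of Se and Sp", {
  set.seed(21)
  for (i in 1:300) {
    tp <- sample(0:50, 1) + 1; tn <- sample(0:50, 1) + 1
    fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    cc <- new("ConfusionCounts", tp = tp, tn = tn, fp = fp, fn = fn)
    # rational identity on integer counts (exact integer arithmetic):
    # 1 - (FP/(FP+TN) + FN/(FN+TP))/2 == (Se + Sp)/2 cross-multiplied
    lhsNum <- 2 * (fp + tn) * (fn + tp) - fp * (fn + tp) - fn * (fp + tn)
    rhsNum <- tp * (tn + fp) + tn * (tp + fn)
    expect_identical(lhsNum, rhsNum)
    expect_equal(aucClosedForm(cc),
      (sensitivity(cc) + specificity(cc)) / 2, tolerance = 1e-12)
  }
})

test_that("adding a true positive never decreases Se, Acc, F1 or AUC", {
  set.seed(8)
  for (i in 1:50) {
    base <- new("ConfusionCounts", tp = sample(1:20, 1), tn = sample(1:20, 1),
      fp = sample(0:20, 1), fn = sample(1:20, 1))
    more <- new("ConfusionCounts", tp = base@tp + 1, tn = base@tn,
      fp = base@fp, fn = base@fn)
    expect_gte(sensitivity(more), sensitivity(base))
    expect_gte(accuracy(more), accuracy(base))
    expect_gte(f1Score(more), f1Score(base))
    expect_gte(aucClosedForm(more), aucClosedForm(base))
  }
})

test_that("binarisation thresholds strictly and validates its input", {
  expect_true(all(binarizePrediction(matrix(0.5, 4, 4), 0.5) == 0))
  expect_equal(as.vector(binarizePrediction(matrix(c(0.2, 0.9), 1, 2), 0.5)),
    c(0, 1))
  m <- matrix(c(0, 0.01, 0.99, 1), 2, 2)
  expect_equal(sum(binarizePrediction(m, 0)), 3)  # all prob > 0
  expect_error(binarizePrediction(matrix(1.2, 2, 2)), "\\[0, 1\\]")
})

test_that("dataset evaluation averages per-image metrics", {
  # two constructed images with Se 0.8 and 0.6
  g <- matrix(0, 10, 10); g[1, 1:10] <- 1
  p1 <- g; p1[1, 9:10] <- 0   # 8 of 10 vessels found
  p2 <- g; p2[1, 7:10] <- 0   # 6 of 10
  rep <- evaluateDataset(list(p1, p2), list(g, g))
  expect_equal(nrow(rep@perImage), 2L)
  expect_equal(rep@perImage$Se, c(0.8, 0.6))
  expect_equal(rep@mean[["Se"]], 0.7)

  one <- evaluateDataset(list(p1), list(g))
  expect_equal(one@mean[["Se"]], one@perImage$Se)

  # undefined per-image values are excluded from the mean with a log
  empty <- matrix(0, 10, 10)
  expect_message(
    rep2 <- evaluateDataset(list(p1, empty), list(g, empty)),
    "undefined")
  expect_equal(rep2@undefinedCounts[["Se"]], 1L)
  expect_equal(rep2@mean[["Se"]], 0.8)

  # pooled aggregation pools counts before dividing
  rep3 <- evaluateDataset(list(p1, p2), list(g, g), pooled = TRUE)
  expect_equal(attr(rep3, "pooled")[["Se"]], 14 / 20)

  expect_error(evaluateDataset(list(p1), list(g, g)), "misaligned")
  expect_error(evaluateDataset(list(), list()), "no predictions")
})

test_that("ROC AUC separates a perfectly ranked probability map", {
  set.seed(3)
  g <- matrix(rbinom(100, 1, 0.4), 10, 10)
  prob <- g * 0.9 + (1 - g) * 0.1
  expect_equal(rocAuc(prob, g), 1)
  # and is near chance for a constant-independent map
  expect_lt(abs(rocAuc(matrix(runif(100), 10, 10), g) - 0.5), 0.25)
})

test_that("error overlays colour-code the confusion classes", {
  g <- matrix(0, 6, 6); g[2:4, 2:4] <- 1
  ov <- renderErrorOverlay(g, g)
  expect_equal(sum(ov[, , 2] == 1), 9)       # TP green
  expect_equal(sum(ov[, , 1]) + sum(ov[, , 3]), 0)

  ovFn <- renderErrorOverlay(matrix(0, 6, 6), g)
  expect_equal(sum(ovFn[, , 3] == 1), 9)     # FN blue

  set.seed(44)
  p <- matrix(rbinom(64, 1, 0.5), 8, 8)
  q <- matrix(rbinom(64, 1, 0.5), 8, 8)
  cc <- confusionCounts(p, q)
  ov2 <- renderErrorOverlay(p, q)
  expect_equal(sum(ov2[, , 2]), cc@tp)
  expect_equal(sum(ov2[, , 1]), cc@fp)
  expect_equal(sum(ov2[, , 3]), cc@fn)
  # TN pixels stay black across all three channels
  expect_equal(sum(ov2[, , 1] == 0 & ov2[, , 2] == 0 & ov2[, , 3] == 0),
    cc@tn)
  expect_error(renderErrorOverlay(p, q[1:4, ]), "shapes differ")
})
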