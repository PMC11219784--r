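test_that("raster formats read to [0,1] RGB arrays of the file's shape", {
  # PNG zero case
  f <- tempfile(fileext = ".png")
  png::writePNG(array(0, c(8, 8, 3)), f)
  img <- readFundusImage(f)
  expect_equal(dim(img), c(8L, 8L, 3L))
  expect_true(all(img == 0))

  # TIFF at DRIVE's native resolution keeps its shape
  f2 <- tempfile(fileext = ".tif")
  set.seed(4)
  tiff::writeTIFF(array(runif(584 * 565 * 3), c(584, 565, 3)), f2)
  expect_equal(dim(readFundusImage(f2)), c(584L, 565L, 3L))

  # grayscale is replicated to 3 channels
  f3 <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 4, 4), f3)
  img3 <- readFundusImage(f3)
  expect_equal(dim(img3), c(4L, 4L, 3L))
  expect_equal(img3[, , 1], img3[, , 3])

  expect_error(readFundusImage(tempfile(fileext = ".png")), "no such file")
  bad <- tempfile(fileext = ".xyz"); writeLines("x", bad)
  expect_error(readFundusImage(bad), "unsupported")
})

test_that("16-bit grayscale PPM at the format maximum reads as all ones", {
  # oracle: integer samples divide by the format max and replicate to RGB
  f <- tempfile(fileext = ".pgm")
  con <- file(f, "wb")
  writeChar("P5\n3 2\n65535\n", con, eos = NULL)
  writeBin(rep(65535L, 6), con, size = 2, endian = "big")
  close(con)
  img <- readFundusImage(f)
  expect_equal(dim(img), c(2L, 3L, 3L))
  expect_true(all(img == 1))

  # ASCII P3 colour round-trips against the binary writer
  f2 <- tempfile(fileext = ".ppm")
  writeLines(c("P3", "2 2", "255",
    paste(as.character(c(255, 0, 0, 0, 255, 0, 0, 0, 255, 10, 20, 30)),
      collapse = " ")), f2)
  img2 <- readFundusImage(f2)
  expect_equal(img2[1, 1, ], c(1, 0, 0))
  expect_equal(img2[2, 2, ], c(10, 20, 30) / 255)
})

test_that("mask writing is a lossless round trip and rejects non-binary", {
  set.seed(99)
  m <- matrix(rbinom(64 * 64, 1, 0.4), 64, 64)
  f <- tempfile(fileext = ".png")
  writeMask(m, f)
  expect_identical(readMask(f), m * 1)

  z <- matrix(0, 512, 512)
  f2 <- tempfile(fileext = ".png")
  writeMask(z, f2)
  expect_true(all(readMask(f2) == 0))

  expect_error(writeMask(matrix(0.5, 2, 2), tempfile(fileext = ".png")),
    "binary")
})

test_that("resizing standardises the frame and keeps masks binary", {
  s <- randomSample(584, 565, seed = 2, withFov = TRUE)
  r <- resizeToInput(s, 512L)
  expect_equal(dim(r@image), c(512L, 512L, 3L))
  expect_equal(dim(r@vesselMask), c(512L, 512L))
  expect_true(all(r@vesselMask %in% c(0, 1)))
  expect_equal(r@sourceResolution, c(584L, 565L))

  # identity resize is bit-identical
  s2 <- randomSample(64, 64, seed = 3)
  expect_identical(resizeToInput(s2, 64L), s2)

  # nearest-neighbour upscale of a checkerboard: each pixel becomes a
  # 2x2 block (manual expansion oracle)
  cb <- (outer(1:4, 1:4, "+") %% 2) * 1
  s3 <- fundusSample("cb", array(0.5, c(4, 4, 3)), cb)
  r3 <- resizeToInput(s3, 8L)
  expect_identical(r3@vesselMask, cb[rep(1:4, each = 2), rep(1:4, each = 2)])

  expect_error(resizeToInput(s2, 70), "divisible by 4")
})

test_that("down-up resize preserves vessel area within discretisation error", {
  s <- smallSynthSample(seed = 6, side = 128L)
  down <- resizeToInput(s, 64L)
  up <- resizeToInput(down, 128L)
  n0 <- sum(s@vesselMask); n1 <- sum(up@vesselMask)
  expect_lt(abs(n1 - n0) / n0, 0.35)
})

test_that("splits honour the declared protocol and partition the ids", {
  ids <- sprintf("im%02d", 1:40)
  drive <- datasetSpec("drive", ids, "fixed_train_test",
    trainIds = ids[1:20], testIds = ids[21:40])
  sp <- makeSplits(drive)
  expect_length(sp, 1L)
  expect_length(sp[[1]]$train, 20L)
  expect_length(sp[[1]]$test, 20L)

  loo <- datasetSpec("stare", ids[1:20], "leave_one_out")
  sp2 <- makeSplits(loo)
  expect_length(sp2, 20L)
  expect_true(all(vapply(sp2, function(p) length(p$train) == 19L, logical(1))))
  expect_equal(vapply(sp2, function(p) p$test, character(1)), ids[1:20])

  sp3 <- makeSplits(datasetSpec("mini", c("a", "b"), "leave_one_out"))
  expect_length(sp3, 2L)
  expect_equal(sp3[[1]]$train, "b")

  # exhaustive and disjoint for every pair of both modes
  universes <- list(ids, ids[1:20], c("a", "b"))
  allPairs <- list(sp, sp2, sp3)
  for (j in seq_along(allPairs)) for (p in allPairs[[j]]) {
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), universes[[j]])
  }

  expect_error(datasetSpec("empty", character(), "fixed_train_test"),
    "at least one")
  expect_error(datasetSpec("single", "a", "leave_one_out"), "at least 2")
})

test_that("dataset directories are read into aligned samples", {
  root <- tempfile(); dir.create(file.path(root, "img"), recursive = TRUE)
  dir.create(file.path(root, "msk"))
  for (i in 1:2) {
    png::writePNG(array(runif(48), c(4, 4, 3)),
      file.path(root, "img", sprintf("s%d.png", i)))
    writeMask(matrix(rbinom(16, 1, 0.5), 4, 4),
      file.path(root, "msk", sprintf("s%d.png", i)))
  }
  ds <- readDataset(file.path(root, "img"), file.path(root, "msk"))
  expect_length(ds, 2L)
  expect_equal(sampleId(ds[[1]]), "s1")
  expect_silent(validObject(ds[[2]]))
})
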