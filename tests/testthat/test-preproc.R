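test_that("crop extracts the requested region unchanged", {
  big <- matrix(stats::runif(2012 * 2012), 2012, 2012)
  out <- cropCenter(big, 512)
  expect_equal(dim(out), c(512, 512))
  x0 <- floor((2012 - 512) / 2) + 1
  expect_identical(out, big[x0:(x0 + 511), x0:(x0 + 511)])
  expect_identical(cropImage(big, c(1, 1, 2012, 2012)), big)
  out488 <- cropCenter(big, 488)
  expect_equal(dim(out488), c(488, 488))
  expect_error(cropImage(big, c(2000, 1, 512, 512)), "bounds")
  rm(big)
})

test_that("resize hits the requested sizes and preserves constants", {
  img <- matrix(stats::runif(512 * 512), 512, 512)
  expect_equal(dim(resizeImage(img, 256)), c(256, 256))
  expect_equal(dim(resizeImage(img, 64)), c(64, 64))
  small <- matrix(stats::runif(64 * 64), 64, 64)
  expect_equal(resizeImage(small, 64, method = "nearest"), small)
  const <- matrix(0.4, 100, 100)
  for (m in c("area", "bilinear", "nearest")) {
    out <- resizeImage(const, 37, method = m)
    expect_true(all(abs(out - 0.4) < 1e-12))
  }
  expect_error(resizeImage(small, 4), ">= 8")
})

test_that("area resize averages exact pixel blocks at integer factors", {
  img <- matrix(as.numeric(1:16), 4, 4)
  out <- resizeImage(matrix(as.numeric(1:64), 8, 8), 8, method = "area")
  expect_equal(out, matrix(as.numeric(1:64), 8, 8))
  big <- matrix(0, 16, 16)
  big[1:8, 1:8] <- 1
  out <- resizeImage(big, 8, method = "area")
  expect_true(all(out[1:4, 1:4] == 1))
  expect_true(all(out[5:8, ] == 0))
})

test_that("Sobel magnitude matches a hand convolution", {
  const <- matrix(0.7, 10, 10)
  # zero up to accumulation rounding of the cancelling kernel terms
  expect_lt(max(abs(sobelMagnitude(const))), 1e-13)

  step <- matrix(0, 9, 9)
  step[, 5:9] <- 1
  out <- sobelMagnitude(step)
  expect_true(all(out[, 4] > 0) && all(out[, 5] > 0))
  expect_true(all(out[, c(1, 2, 8, 9)] == 0))

  set.seed(31)
  ramp <- outer(1:5, 1:5, function(i, j) 0.1 * i + 0.05 * j)
  expect_equal(sobelMagnitude(ramp), bruteSobel(ramp), tolerance = 1e-12)
  noisy <- matrix(stats::runif(49), 7, 7)
  expect_equal(sobelMagnitude(noisy), bruteSobel(noisy), tolerance = 1e-12)
})

test_that("local entropy evaluates the histogram entropy exactly", {
  const <- matrix(0.3, 8, 8)
  expect_true(all(localEntropy(const, windowSpec("square", 3), bins = 256) == 0))

  # 3x3 window whose 9 pixels land in 9 distinct bins -> ln 9
  img <- matrix(seq(0.05, 0.85, by = 0.1), 3, 3)
  h <- localEntropy(img, windowSpec("square", 3), bins = 9, range = c(0, 0.9))
  expect_equal(h[2, 2], log(9), tolerance = 1e-12)

  # 5 pixels in one bin, 4 in another
  img2 <- matrix(c(rep(0.1, 5), rep(0.9, 4)), 3, 3)
  h2 <- localEntropy(img2, windowSpec("square", 3), bins = 2)
  expect_equal(h2[2, 2], -(5 / 9) * log(5 / 9) - (4 / 9) * log(4 / 9),
               tolerance = 1e-12)

  # base-2 option divides by ln 2
  h2b <- localEntropy(img2, windowSpec("square", 3), bins = 2, base = 2)
  expect_equal(h2b[2, 2], h2[2, 2] / log(2), tolerance = 1e-12)
})

test_that("entropy output is bounded by log(bins) for arbitrary inputs", {
  set.seed(5)
  for (bins in c(4, 16, 256)) {
    img <- matrix(stats::runif(400), 20, 20)
    h <- localEntropy(img, windowSpec("disk", 3), bins = bins)
    expect_true(all(h >= 0))
    expect_true(all(h <= log(bins) + 1e-12))
  }
})

test_that("local mean and median behave on canonical inputs", {
  const <- matrix(0.25, 10, 10)
  expect_equal(localMean(const), const)
  expect_equal(localMedian(const), const)

  spike <- matrix(0, 9, 9)
  spike[5, 5] <- 1
  expect_true(all(localMedian(spike) == 0))

  patch <- matrix(c(
    1, 2, 3, 4, 5,
    2, 3, 4, 5, 6,
    3, 4, 5, 6, 7,
    4, 5, 6, 7, 8,
    5, 6, 7, 8, 9
  ), 5, 5, byrow = TRUE)
  m <- localMean(patch, windowSpec("square", 3))
  expect_equal(m[3, 3], mean(patch[2:4, 2:4]))
  expect_equal(m[2, 2], mean(patch[1:3, 1:3]))
})

test_that("fast filters agree with the brute-force oracle", {
  set.seed(123)
  for (rep in 1:20) {
    img <- matrix(stats::runif(256), 16, 16)
    w <- if (rep %% 2 == 0) windowSpec("square", 3) else windowSpec("disk", 2)
    if (rep %% 3 == 0) w <- windowSpec("square", 5, border = "constant", value = 0.5)
    expect_equal(localMean(img, w), bruteLocalFilter(img, w, "mean"),
                 tolerance = 1e-10)
    expect_equal(localMedian(img, w), bruteLocalFilter(img, w, "median"),
                 tolerance = 1e-10)
    expect_equal(localEntropy(img, w, bins = 16),
                 bruteLocalFilter(img, w, "entropy", bins = 16),
                 tolerance = 1e-10)
  }
})

test_that("pipelines compose, record provenance, and name failing steps", {
  img <- matrix(stats::runif(600 * 600), 600, 600)
  out <- applyPipeline(img, preprocSpec())
  expect_equal(dim(out), dim(img))
  expect_equal(as.vector(out), as.vector(img))

  spec <- preprocSpec(
    list(op = "cropCenter", side = 512),
    list(op = "resize", side = 256),
    list(op = "entropy", window = list(shape = "disk", size = 5), bins = 256)
  )
  out <- applyPipeline(img, spec)
  expect_equal(dim(out), c(256, 256))
  expect_true(all(out <= log(256)))
  expect_length(attr(out, "provenance"), 3)

  spec2 <- preprocSpec(list(op = "cropCenter", side = 512),
                       list(op = "resize", side = 64))
  expect_equal(dim(applyPipeline(img, spec2)), c(64, 64))

  bad <- preprocSpec(list(op = "resize", side = 256),
                     list(op = "crop", roi = c(300, 1, 100, 100)))
  expect_error(applyPipeline(img, bad), "step 2 \\(crop\\)")
  expect_error(preprocSpec(list(op = "sharpen")), "unknown preprocessing op")
})

test_that("entropy filtering highlights a region boundary more than mean or median", {
  # two constant regions plus uniform noise: the entropy output responds at
  # the boundary (wider local distribution) while mean/median outputs keep
  # the plateau gray levels, so their boundary band does not stand out from
  # the average of the two interiors
  set.seed(77)
  img <- matrix(0.3, 64, 64)
  img[, 33:64] <- 0.7
  img <- img + matrix(stats::runif(64 * 64, -0.15, 0.15), 64, 64)
  w <- windowSpec("disk", 4)
  bandGap <- function(x) {
    boundary <- mean(x[, 29:36])
    interior <- mean(c(x[, 6:13], x[, 52:59]))
    (boundary - interior) / diff(range(x))
  }
  gapEntropy <- bandGap(localEntropy(img, w, bins = 64))
  gapMean <- bandGap(localMean(img, w))
  gapMedian <- bandGap(localMedian(img, w))
  expect_gt(gapEntropy, 0.1)
  expect_gt(gapEntropy, abs(gapMean))
  expect_gt(gapEntropy, abs(gapMedian))
})

test_that("pipeline specs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(steps = list(
    list(op = "cropCenter", side = 100),
    list(op = "entropy", window = list(shape = "square", size = 5), bins = 32)
  )), path)
  spec <- readPreprocSpec(path)
  expect_s3_class(spec, "preprocSpec")
  img <- matrix(stats::runif(120 * 120), 120, 120)
  out <- applyPipeline(img, spec)
  expect_equal(dim(out), c(100, 100))
  expect_true(all(out <= log(32)))
  unlink(path)
})
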