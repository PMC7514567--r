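tinyConfig <- function(side = 16, dropout = 0) {
  modelConfig(
    inputSide = side,
    convBlocks = data.frame(filters = c(4, 6), kernel = 3, pool = 2,
                            dropout = dropout),
    denseWidth = 8, denseDropout = dropout
  )
}

tinyData <- function(n = 24, side = 16, seed = 2) {
  # class = brightness level; trivially separable
  set.seed(seed)
  y <- rep(1:6, length.out = n)
  x <- array(0, dim = c(side, side, n))
  for (i in seq_len(n)) {
    x[, , i] <- y[i] / 6 + matrix(stats::rnorm(side^2, 0, 0.02), side, side)
  }
  list(x = x, y = y)
}

test_that("categorical cross-entropy matches its closed forms", {
  Y <- diag(6)
  expect_equal(categoricalCrossEntropy(Y, Y), 0)
  U <- matrix(1 / 6, 6, 6)
  expect_equal(categoricalCrossEntropy(Y, U), log(6), tolerance = 1e-12)
  Y1 <- matrix(c(1, 0), 1, 2)
  P1 <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(categoricalCrossEntropy(Y1, P1), log(2), tolerance = 1e-12)
  expect_equal(categoricalCrossEntropy(Y, U, reduction = "sum"), 6 * log(6),
               tolerance = 1e-12)
  expect_error(categoricalCrossEntropy(Y, U[1:3, ]), "shape")
  expect_error(categoricalCrossEntropy(Y, U * 2), "sum to 1")
  expect_error(categoricalCrossEntropy(Y * 0.5, U), "one-hot")
})

test_that("cross-entropy agrees with a scalar double loop on random inputs", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    k <- sample(2:8, 1)
    Y <- randomOneHot(n, k)
    P <- randomProbMatrix(n, k)
    expect_equal(categoricalCrossEntropy(Y, P), bruteCrossEntropy(Y, P),
                 tolerance = 1e-10)
    expect_equal(categoricalCrossEntropy(Y, P, reduction = "sum"),
                 bruteCrossEntropy(Y, P, reduction = "sum"),
                 tolerance = 1e-10)
  }
})

test_that("the built network has the documented structure and parameter count", {
  cfg <- modelConfig(inputSide = 64)
  expect_equal(nrow(cfg$convBlocks), 5)
  set.seed(1)
  net <- buildModel(cfg)
  # closed-form count: conv (Cin*9+1)*Cout, bn 2*C per block;
  # dense 512*1024+1024, bn 2*1024, dense 1024*6+6
  convs <- c(1, 32, 64, 64, 128)
  filt <- c(32, 64, 64, 128, 128)
  expected <- sum((convs * 9 + 1) * filt) + sum(2 * filt) +
    512 * 1024 + 1024 + 2 * 1024 + 1024 * 6 + 6
  expect_equal(nParams(net), expected)

  # hand count on a small config as an independent check
  set.seed(1)
  small <- buildModel(tinyConfig())
  handCount <- (1 * 9 + 1) * 4 + 2 * 4 +   # block 1
    (4 * 9 + 1) * 6 + 2 * 6 +              # block 2
    (4 * 4 * 6) * 8 + 8 + 2 * 8 +          # dense block (16/2/2 = 4)
    8 * 6 + 6                              # classifier head
  expect_equal(nParams(small), handCount)

  expect_error(modelConfig(inputSide = 50), "not divisible")
})

test_that("predicted probabilities are a valid softmax output", {
  set.seed(3)
  net <- buildModel(tinyConfig())
  x <- array(stats::runif(16 * 16 * 5), dim = c(16, 16, 5))
  p <- predictProba(net, x)
  expect_equal(dim(p), c(5, 6))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  # duplicated image gives identical rows
  x2 <- array(x[, , c(1, 1)], dim = c(16, 16, 2))
  p2 <- predictProba(net, x2)
  expect_identical(p2[1, ], p2[2, ])
})

test_that("the training engine reproduces the reference forward/backward step", {
  set.seed(11)
  cfg <- tinyConfig()
  net1 <- buildModel(cfg)
  net2 <- buildModel(cfg)
  net2@params$values <- net1@params$values
  net2@params$state <- net1@params$state
  d <- tinyData(8)
  tc <- trainConfig(optimizer = "sgd", learningRate = 0.05, momentum = 0,
                    epochs = 1, batchSize = 8, seed = 3, shuffle = FALSE,
                    keepBest = FALSE)
  fit <- trainModel(net1, d, NULL, tc)

  # reference path: plain R orchestration of the double-precision kernels
  xb <- array(d$x, dim = c(16, 16, 1, 8))
  fw <- cvmStager:::.cvmForward(net2, xb, training = TRUE, keepCache = TRUE)
  lossRef <- cvmStager:::.batchLoss(fw$probs, d$y)
  g <- cvmStager:::.cvmBackward(net2, fw$cache, d$y)
  opt <- cvmStager:::.newOptState(net2@params$values, tc, 0.05)
  cvmStager:::.optimStep(net2, g, tc, opt)

  expect_equal(fit$history$train_loss[1], lossRef, tolerance = 1e-5)
  for (nm in names(net1@params$values)) {
    expect_equal(net1@params$values[[nm]], net2@params$values[[nm]],
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("a zero learning rate leaves parameters unchanged", {
  set.seed(21)
  net <- buildModel(tinyConfig())
  before <- net@params$values
  d <- tinyData(12)
  tc <- trainConfig(optimizer = "sgd", learningRate = 0, momentum = 0.9,
                    epochs = 2, batchSize = 12, seed = 5, shuffle = FALSE,
                    keepBest = FALSE)
  fit <- trainModel(net, d, NULL, tc)
  for (nm in names(before)) {
    expect_equal(net@params$values[[nm]], before[[nm]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # with one batch, no dropout and frozen weights the two epoch losses match
  expect_equal(fit$history$train_loss[1], fit$history$train_loss[2])
})

test_that("training is deterministic under a fixed seed", {
  d <- tinyData(24)
  run <- function() {
    set.seed(33)
    net <- buildModel(tinyConfig(dropout = 0.2))
    trainModel(net, d, d, trainConfig(epochs = 3, seed = 7))$history
  }
  expect_identical(run(), run())
})

test_that("training reduces the loss on separable data", {
  d <- tinyData(96)
  set.seed(5)
  net <- buildModel(modelConfig(
    inputSide = 16,
    convBlocks = data.frame(filters = c(8, 8), kernel = 3, pool = 2,
                            dropout = 0),
    denseWidth = 32, denseDropout = 0
  ))
  fit <- trainModel(net, d, NULL, trainConfig(epochs = 30, seed = 5))
  h <- fit$history
  expect_lt(h$train_loss[30], h$train_loss[1])
  expect_gte(h$train_accuracy[30], 0.9)
})

test_that("a non-finite loss aborts with a diagnostic naming the batch", {
  d <- tinyData(12)
  set.seed(6)
  net <- buildModel(tinyConfig())
  net@params$values$dense2_W[] <- NaN  # corrupted checkpoint
  expect_error(
    trainModel(net, d, NULL, trainConfig(epochs = 3, seed = 1)),
    "epoch 1, batch 1"
  )
})

test_that("the LR range test follows the exponential schedule exactly", {
  d <- tinyData(16)
  set.seed(9)
  net <- buildModel(tinyConfig())
  before <- net@params$values
  res <- lrRangeTest(net, d, lrBounds = c(0.1, 10), nSteps = 25, batchSize = 8)
  expect_equal(res$learning_rate[1], 0.1)
  expect_equal(res$learning_rate[25], 10)
  ratios <- res$learning_rate[-1] / res$learning_rate[-25]
  expect_true(all(abs(ratios - ratios[1]) < 1e-10))
  expect_true(all(is.finite(res$loss) | is.na(res$loss)))
  # model restored afterwards
  for (nm in names(before)) {
    expect_identical(net@params$values[[nm]], before[[nm]])
  }

  res2 <- lrRangeTest(net, d, lrBounds = c(0.1, 10), nSteps = 2, batchSize = 8)
  expect_equal(res2$learning_rate, c(0.1, 10))
  expect_error(lrRangeTest(net, d, nSteps = 1), ">= 2")
  expect_error(lrRangeTest(net, d, lrBounds = c(1, 0.5)), "low < high")
})

test_that("selectLR picks the steepest smoothed loss decrease", {
  mk <- function(losses) {
    structure(data.frame(step = seq_along(losses),
                         learning_rate = 10^seq(-3, 0, length.out = length(losses)),
                         loss = losses),
              class = c("lrRangeResult", "data.frame"))
  }
  r <- mk(c(3, 3, 2.5, 1, 0.9, 2))
  expect_equal(selectLR(r, window = 1), r$learning_rate[4])

  flat <- mk(rep(2, 6))
  expect_warning(lr <- selectLR(flat, window = 1), "never decreases")
  expect_equal(lr, flat$learning_rate[1])

  two <- mk(c(2, 1))
  expect_equal(selectLR(two, window = 1), two$learning_rate[2])
})

test_that("self-training moves exactly the confident, correct pool samples", {
  d <- tinyData(60)
  set.seed(12)
  net <- buildModel(tinyConfig())
  trainModel(net, d, NULL, trainConfig(epochs = 20, seed = 12))
  pool <- tinyData(30, seed = 77)
  p <- predictProba(net, pool$x)
  pred <- max.col(p, ties.method = "first")
  maxp <- p[cbind(seq_len(30), pred)]
  thr <- stats::median(maxp)  # guarantees a mixed pool
  expectMove <- pred == pool$y & maxp >= thr

  res <- selfTrainingUpdate(net, d, pool, probThreshold = thr)
  expect_equal(res$log$moved, expectMove)
  expect_equal(length(res$pool$y), sum(!expectMove))
  expect_equal(length(res$train$y), 60 + sum(expectMove))
  expect_equal(dim(res$train$x)[3], 60 + sum(expectMove))

  # threshold 1 with imperfect probabilities moves nothing
  if (all(maxp < 1)) {
    res1 <- selfTrainingUpdate(net, d, pool, probThreshold = 1)
    expect_equal(sum(res1$log$moved), 0)
  }
  expect_error(selfTrainingUpdate(net, d, pool, probThreshold = 1.5),
               "probThreshold")

  empty <- list(x = array(0, dim = c(16, 16, 0)), y = integer(0))
  expect_message(res0 <- selfTrainingUpdate(net, d, empty), "empty")
  expect_equal(length(res0$train$y), 60)
})

test_that("best-validation checkpoint tracks the history", {
  d <- tinyData(36)
  set.seed(8)
  net <- buildModel(tinyConfig(dropout = 0.1))
  fit <- trainModel(net, d, d, trainConfig(epochs = 6, seed = 8, keepBest = TRUE))
  expect_false(is.null(fit$best))
  expect_equal(fit$best$valAccuracy, max(fit$history$val_accuracy))
  expect_equal(fit$best$epoch,
               which.max(fit$history$val_accuracy))
})

test_that("models save and load with an identical forward pass", {
  set.seed(4)
  net <- buildModel(tinyConfig())
  path <- tempfile(fileext = ".rds")
  saveModel(net, path, meta = list(seed = 4))
  expect_true(file.exists(sub("rds$", "json", path)))
  net2 <- loadModel(path)
  x <- array(stats::runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_identical(predictProba(net, x), predictProba(net2, x))
  unlink(c(path, sub("rds$", "json", path)))
})
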