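# Shared drivers for the end-to-end synthetic benchmarks; results are cached
# so several tests can reuse the same trained runs.

.benchCache <- new.env(parent = emptyenv())

# Standard synthetic benchmark: easy preset, 100 images/class rendered at
# 128 px, resized to the 64-px model input, 30 epochs.
benchmarkAccuracy <- function(seed, blocks = 5) {
  key <- sprintf("b%d_s%d", blocks, seed)
  if (!is.null(.benchCache[[key]])) return(.benchCache[[key]])
  cfg <- cvmPreset("easy", imageSize = 128, nPerClass = 100, seed = seed)
  ds <- generateDataset(cfg)
  ds <- preprocessDataset(ds, preprocSpec(list(op = "resize", side = 64)))
  mcfg <- modelConfig(inputSide = 64)
  if (blocks == 6) mcfg <- deeperConfig(mcfg)
  set.seed(seed)
  net <- buildModel(mcfg)
  fit <- trainModel(net, modelInput(ds, "train"), modelInput(ds, "validation"),
                    trainConfig(epochs = 30, seed = seed))
  net <- restoreBestCheckpoint(net, fit)
  test <- modelInput(ds, "test")
  acc <- mean(stageIndex(predictStage(net, test$x)) == test$y)
  .benchCache[[key]] <- list(accuracy = acc, history = fit$history)
  .benchCache[[key]]
}

# Hard-preset comparison at reduced scale: 50 images/class rendered at
# 128 px, model input 64 px, 12 epochs; inputs either entropy-filtered at
# render scale (then resized) or raw (resized only).
hardPresetAccuracy <- function(seed, filter = c("raw", "entropy")) {
  filter <- match.arg(filter)
  key <- sprintf("h_%s_s%d", filter, seed)
  if (!is.null(.benchCache[[key]])) return(.benchCache[[key]])
  cfg <- cvmPreset("hard", imageSize = 128, nPerClass = 50, seed = seed)
  ds <- generateDataset(cfg)
  spec <- if (filter == "entropy") {
    preprocSpec(
      list(op = "entropy", window = list(shape = "disk", size = 3),
           bins = 64, normalize = TRUE),
      list(op = "resize", side = 64)
    )
  } else {
    preprocSpec(list(op = "resize", side = 64))
  }
  ds <- preprocessDataset(ds, spec)
  set.seed(seed)
  net <- buildModel(modelConfig(inputSide = 64))
  fit <- trainModel(net, modelInput(ds, "train"), modelInput(ds, "validation"),
                    trainConfig(epochs = 12, seed = seed))
  net <- restoreBestCheckpoint(net, fit)
  test <- modelInput(ds, "test")
  acc <- mean(stageIndex(predictStage(net, test$x)) == test$y)
  .benchCache[[key]] <- acc
  acc
}

# A published CVM staging confusion matrix (900 test images, 150 per class),
# used as a worked example for the report arithmetic.
publishedConfusionMatrix <- function() {
  matrix(c(
    101,   6,   4,  25,  12,   2,
      0, 110,   3,  30,   5,   2,
      0,   0, 122,  22,   6,   0,
      0,   0,   0, 148,   2,   0,
      1,   1,   1,   8, 139,   0,
      0,   0,   0,  16,   2, 132
  ), nrow = 6, byrow = TRUE,
  dimnames = list(true = paste0("CS", 1:6), predicted = paste0("CS", 1:6)))
}

publishedReport <- function() {
  data.frame(
    class = paste0("CS", 1:6),
    precision = c(0.99, 0.94, 0.94, 0.59, 0.84, 0.97),
    recall = c(0.67, 0.73, 0.81, 0.99, 0.93, 0.88),
    f1 = c(0.80, 0.82, 0.87, 0.74, 0.88, 0.92),
    support = c(150, 150, 150, 150, 150, 150)
  )
}
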