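# End-to-end orchestration: generate (or load) data, preprocess, train,
# evaluate, and write all run artifacts into a run directory.

#' Default run configuration
#'
#' The standard synthetic benchmark: 100 images per class rendered at
#' 128 px under the easy preset, resized to the 64-px model input, the
#' default five-block network, and 30 training epochs.
#'
#' @param seed seed propagated to the generator and trainer.
#' @return Nested list understood by [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    generator = list(preset = "easy", imageSize = 128, nPerClass = 100,
                     seed = seed),
    splits = c(train = 0.6, validation = 0.2, test = 0.2),
    preprocessing = list(list(op = "resize", side = 64)),
    model = list(inputSide = 64),
    training = list(optimizer = "adam", learningRate = 3e-3, epochs = 30,
                    batchSize = 32, seed = seed),
    rules = list(),
    writeImages = FALSE,
    logLevel = "info"
  )
}

#' Read a run configuration from YAML
#' @param path YAML file; missing fields fall back to [defaultRunConfig()].
#' @return Nested run configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (nm in names(y)) cfg[[nm]] <- y[[nm]]
  cfg
}

.resolveGenerator <- function(g) {
  preset <- if (is.null(g$preset)) "easy" else g$preset
  g$preset <- NULL
  do.call(cvmPreset, c(list(name = preset), g))
}

.log <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full staging pipeline
#'
#' Generates the synthetic dataset, applies the preprocessing pipeline,
#' trains the compact CNN, evaluates on the test split, and writes into
#' `outputDir`: the dataset manifest, training history CSV, model
#' checkpoint with its JSON sidecar, confusion matrix CSV, report JSON,
#' probability-grid images/CSVs, and a frozen copy of the resolved
#' configuration. Runs are reproducible from the frozen configuration and
#' seed alone; an existing non-empty output directory is never silently
#' overwritten.
#'
#' @param config nested list as from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param outputDir run directory to create.
#' @param seed optional override propagated to generator and trainer.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The run directory path, invisibly; the evaluation summary is
#'   written to `report.json`.
#' @export
runPipeline <- function(config = defaultRunConfig(), outputDir,
                        seed = NULL, overwrite = FALSE) {
  if (!is.null(seed)) {
    config$generator$seed <- seed
    config$training$seed <- seed
  }
  if (dir.exists(outputDir) && length(list.files(outputDir)) > 0 &&
      !overwrite) {
    stop("output directory exists and is not empty: ", outputDir)
  }
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(outputDir, "run.log"), open = "wt")
  on.exit(close(logCon), add = TRUE)

  gen <- .resolveGenerator(config$generator)
  yaml::write_yaml(
    c(config, list(resolvedGenerator = generatorConfigAsList(gen))),
    file.path(outputDir, "config.yaml")
  )
  .log(logCon, "generating %d images per class at %d px",
       as.integer(gen@nPerClass), as.integer(gen@imageSize))
  splits <- unlist(config$splits)
  ds <- generateDataset(
    gen, splitFractions = splits,
    dir = if (isTRUE(config$writeImages)) file.path(outputDir, "images") else NULL
  )
  utils::write.csv(manifest(ds), file.path(outputDir, "manifest.csv"),
                   row.names = FALSE)

  if (length(config$preprocessing) > 0) {
    .log(logCon, "preprocessing: %s",
         paste(vapply(config$preprocessing, function(s) s$op, character(1)),
               collapse = " -> "))
    ds <- preprocessDataset(ds, preprocSpec(config$preprocessing))
  }

  mcfg <- do.call(modelConfig, config$model)
  tc <- do.call(trainConfig, config$training)
  set.seed(as.integer(tc$seed))
  net <- buildModel(mcfg)
  .log(logCon, "training %d-block model (%d parameters) for %d epochs",
       nrow(mcfg$convBlocks), nParams(net), tc$epochs)
  train <- modelInput(ds, "train")
  val <- modelInput(ds, "validation")
  if (length(val$y) == 0) val <- NULL
  fit <- trainModel(net, train, val, tc)
  net <- restoreBestCheckpoint(net, fit)
  if (!is.null(fit$best)) {
    .log(logCon, "using best-validation checkpoint from epoch %d (%.3f)",
         fit$best$epoch, fit$best$valAccuracy)
  }
  utils::write.csv(fit$history, file.path(outputDir, "history.csv"),
                   row.names = FALSE)
  saveModel(net, file.path(outputDir, "checkpoint.rds"),
            meta = list(training = unclass(tc),
                        generatorSeed = gen@seed))

  test <- modelInput(ds, "test")
  if (length(test$y) == 0) {
    .log(logCon, "test split is empty: evaluation skipped")
    return(invisible(outputDir))
  }
  .log(logCon, "evaluating on %d test images", length(test$y))
  probs <- predictProba(net, test$x)
  pred <- max.col(probs, ties.method = "first")
  cm <- confusionMatrix6(test$y, pred)
  writeConfusionCSV(cm, file.path(outputDir, "confusion.csv"))
  rep <- classificationReport(cm)
  jsonlite::write_json(
    list(
      accuracy = rep$accuracy,
      perClass = rep$perClass,
      perClassAccuracy = as.list(perClassAccuracy(cm)),
      nTest = rep$total
    ),
    file.path(outputDir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  pg <- probabilityGrid(probs, test$y)
  writeProbabilityGrid(pg, file.path(outputDir, "probability_grids"))
  .log(logCon, "test accuracy %.3f", rep$accuracy)
  invisible(outputDir)
}
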