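# Compact CNN classifier: five (configurable) blocks of convolution, batch
# normalization, ReLU, max pooling and dropout, then one dense block and a
# 6-way softmax head. Trained with categorical cross-entropy under SGD
# (momentum) or Adam. Includes the exponential learning-rate range test and
# the confidence-thresholded self-training step.

#' Model configuration
#'
#' The default mirrors the six-layer structure: five convolution blocks
#' (3x3 kernels; 32/64/64/128/128 filters; 2x2 max pooling; dropout rates
#' 0.2/0.2/0.3/0.4/0.5) and one dense block of 1024 units feeding 6 classes.
#'
#' @param inputSide input image side in pixels; must be divisible by the
#'   product of the pooling factors.
#' @param convBlocks data.frame with columns `filters`, `kernel`, `pool`,
#'   `dropout` (one row per block).
#' @param denseWidth dense block width in units.
#' @param denseDropout dropout rate of the dense block.
#' @param nClasses number of output classes.
#' @return List of class `modelConfig`.
#' @export
modelConfig <- function(inputSide = 64,
                        convBlocks = data.frame(
                          filters = c(32, 64, 64, 128, 128),
                          kernel = 3, pool = 2,
                          dropout = c(0.2, 0.2, 0.3, 0.4, 0.5)
                        ),
                        denseWidth = 1024, denseDropout = 0.5, nClasses = 6) {
  stopifnot(nrow(convBlocks) >= 1, all(convBlocks$dropout >= 0),
            all(convBlocks$dropout < 1), denseDropout >= 0, denseDropout < 1)
  side <- inputSide
  for (p in convBlocks$pool) {
    if (side %% p != 0) {
      stop("pooling cascade exhausts the spatial size: ", side,
           " not divisible by ", p)
    }
    side <- side / p
  }
  if (side < 1) stop("pooling cascade exhausts the spatial size")
  structure(
    list(inputSide = inputSide, convBlocks = convBlocks,
         denseWidth = denseWidth, denseDropout = denseDropout,
         nClasses = nClasses, finalSide = side),
    class = "modelConfig"
  )
}

#' Add one convolution block to a configuration
#'
#' Appends a block (used for depth comparisons). The new block repeats the
#' last block's filter count and uses the given dropout rate.
#'
#' @param config a [modelConfig()].
#' @param dropout dropout rate of the appended block.
#' @return A new `modelConfig`.
#' @export
deeperConfig <- function(config, dropout = 0.5) {
  cb <- config$convBlocks
  cb <- rbind(cb, cb[nrow(cb), ])
  cb$dropout[nrow(cb)] <- dropout
  modelConfig(config$inputSide, cb, config$denseWidth, config$denseDropout,
              config$nClasses)
}

#' Build the network
#'
#' Initializes all weights (He-scaled Gaussians, using the current RNG
#' state) and returns a handle exposing forward evaluation and the
#' parameter count.
#'
#' @param config a [modelConfig()].
#' @return A [CvmNet].
#' @export
buildModel <- function(config) {
  if (!inherits(config, "modelConfig")) config <- do.call(modelConfig, config)
  values <- list()
  state <- list()
  cin <- 1L
  for (i in seq_len(nrow(config$convBlocks))) {
    b <- config$convBlocks[i, ]
    fanIn <- cin * b$kernel^2
    values[[paste0("conv", i, "_W")]] <-
      matrix(stats::rnorm(fanIn * b$filters, sd = sqrt(2 / fanIn)),
             fanIn, b$filters)
    values[[paste0("conv", i, "_b")]] <- numeric(b$filters)
    values[[paste0("bn", i, "_gamma")]] <- rep(1, b$filters)
    values[[paste0("bn", i, "_beta")]] <- numeric(b$filters)
    state[[paste0("bn", i, "_rmean")]] <- numeric(b$filters)
    state[[paste0("bn", i, "_rvar")]] <- rep(1, b$filters)
    cin <- b$filters
  }
  feat <- config$finalSide^2 * cin
  values$dense1_W <- matrix(
    stats::rnorm(feat * config$denseWidth, sd = sqrt(2 / feat)),
    feat, config$denseWidth
  )
  values$dense1_b <- numeric(config$denseWidth)
  values$bnD_gamma <- rep(1, config$denseWidth)
  values$bnD_beta <- numeric(config$denseWidth)
  state$bnD_rmean <- numeric(config$denseWidth)
  state$bnD_rvar <- rep(1, config$denseWidth)
  values$dense2_W <- matrix(
    stats::rnorm(config$denseWidth * config$nClasses,
                 sd = sqrt(2 / config$denseWidth)),
    config$denseWidth, config$nClasses
  )
  values$dense2_b <- numeric(config$nClasses)
  env <- new.env(parent = emptyenv())
  env$values <- values
  env$state <- state
  new("CvmNet", config = unclass(config), params = env)
}

.bnMomentum <- 0.9
.bnEps <- 1e-5

# Forward pass. x: array (H, W, 1, B). Returns class probabilities (nClasses
# x B) and, when keepCache, everything the backward pass needs.
.cvmForward <- function(net, x, training = FALSE, keepCache = FALSE) {
  v <- net@params$values
  st <- net@params$state
  cfg <- net@config
  nb <- nrow(cfg$convBlocks)
  cache <- if (keepCache) list(blocks = vector("list", nb)) else NULL
  for (i in seq_len(nb)) {
    b <- cfg$convBlocks[i, ]
    dims <- dim(x)
    z <- conv2d_forward_cpp(x, v[[paste0("conv", i, "_W")]],
                            v[[paste0("conv", i, "_b")]],
                            as.integer(dims), as.integer(b$kernel))
    zdims <- dim(z)
    bn <- bn_forward_cpp(z, as.integer(zdims),
                         v[[paste0("bn", i, "_gamma")]],
                         v[[paste0("bn", i, "_beta")]],
                         st[[paste0("bn", i, "_rmean")]],
                         st[[paste0("bn", i, "_rvar")]],
                         .bnEps, training, TRUE)
    if (training) {
      n <- prod(zdims[c(1, 2, 4)])
      ub <- if (n > 1) n / (n - 1) else 1
      net@params$state[[paste0("bn", i, "_rmean")]] <-
        .bnMomentum * st[[paste0("bn", i, "_rmean")]] + (1 - .bnMomentum) * bn$mean
      net@params$state[[paste0("bn", i, "_rvar")]] <-
        .bnMomentum * st[[paste0("bn", i, "_rvar")]] +
        (1 - .bnMomentum) * (1 / bn$invstd^2 - .bnEps) * ub
      st <- net@params$state
    }
    pl <- maxpool_forward_cpp(bn$y, as.integer(zdims), as.integer(b$pool))
    out <- pl$y
    dmask <- NULL
    if (training && b$dropout > 0) {
      dmask <- (stats::runif(length(out)) >= b$dropout) / (1 - b$dropout)
      out <- mul_inplace_cpp(out, dmask)
    }
    if (keepCache) {
      cache$blocks[[i]] <- list(
        xin = x, z = z, zdims = zdims, bnMean = bn$mean, bnInvstd = bn$invstd,
        a = bn$y, poolIdx = pl$idx, pooledDims = dim(pl$y),
        dropMask = dmask
      )
    }
    x <- out
  }
  pooledDims <- dim(x)
  B <- pooledDims[4]
  FF <- matrix(x, nrow = prod(pooledDims[1:3]), ncol = B)
  z1 <- crossprod(v$dense1_W, FF) + v$dense1_b
  dw <- cfg$denseWidth
  bnD <- bn_forward_cpp(z1, c(1L, 1L, dw, B), v$bnD_gamma, v$bnD_beta,
                        st$bnD_rmean, st$bnD_rvar, .bnEps, training, TRUE)
  if (training) {
    ub <- if (B > 1) B / (B - 1) else 1
    net@params$state$bnD_rmean <-
      .bnMomentum * st$bnD_rmean + (1 - .bnMomentum) * bnD$mean
    net@params$state$bnD_rvar <-
      .bnMomentum * st$bnD_rvar + (1 - .bnMomentum) * (1 / bnD$invstd^2 - .bnEps) * ub
  }
  h <- bnD$y
  dim(h) <- c(dw, B)
  hd <- h
  dmask1 <- NULL
  if (training && cfg$denseDropout > 0) {
    dmask1 <- (stats::runif(length(h)) >= cfg$denseDropout) /
      (1 - cfg$denseDropout)
    hd <- h * matrix(dmask1, dw, B)
  }
  z2 <- crossprod(v$dense2_W, hd) + v$dense2_b
  z2 <- z2 - rep(apply(z2, 2, max), each = cfg$nClasses)
  ez <- exp(z2)
  probs <- ez / rep(colSums(ez), each = cfg$nClasses)
  if (keepCache) {
    cache$pooledDims <- pooledDims
    cache$FF <- FF
    cache$z1 <- z1
    cache$bnDMean <- bnD$mean
    cache$bnDInvstd <- bnD$invstd
    cache$h <- h
    cache$dropMask1 <- dmask1
    cache$hd <- hd
    cache$probs <- probs
  }
  list(probs = probs, cache = cache)
}

# Backward pass for mean-reduced cross-entropy. y: integer labels (1-based).
.cvmBackward <- function(net, cache, y) {
  v <- net@params$values
  cfg <- net@config
  B <- length(y)
  g <- list()
  dz2 <- cache$probs
  dz2[cbind(y, seq_len(B))] <- dz2[cbind(y, seq_len(B))] - 1
  dz2 <- dz2 / B
  g$dense2_W <- cache$hd %*% t(dz2)
  g$dense2_b <- rowSums(dz2)
  dh <- v$dense2_W %*% dz2
  if (!is.null(cache$dropMask1)) dh <- dh * matrix(cache$dropMask1, nrow(dh), B)
  dw <- cfg$denseWidth
  bb <- bn_backward_cpp(cache$z1, dh, cache$h, c(1L, 1L, dw, B), v$bnD_gamma,
                        cache$bnDMean, cache$bnDInvstd, TRUE)
  g$bnD_gamma <- bb$dgamma
  g$bnD_beta <- bb$dbeta
  dz1 <- bb$dx
  dim(dz1) <- c(dw, B)
  g$dense1_W <- cache$FF %*% t(dz1)
  g$dense1_b <- rowSums(dz1)
  dx <- v$dense1_W %*% dz1
  dim(dx) <- cache$pooledDims
  for (i in rev(seq_len(nrow(cfg$convBlocks)))) {
    blk <- cache$blocks[[i]]
    b <- cfg$convBlocks[i, ]
    if (!is.null(blk$dropMask)) {
      dx <- mul_inplace_cpp(dx, blk$dropMask)
    }
    dx <- maxpool_backward_cpp(dx, blk$poolIdx, as.integer(blk$zdims))
    bb <- bn_backward_cpp(blk$z, dx, blk$a, as.integer(blk$zdims),
                          v[[paste0("bn", i, "_gamma")]],
                          blk$bnMean, blk$bnInvstd, TRUE)
    g[[paste0("bn", i, "_gamma")]] <- bb$dgamma
    g[[paste0("bn", i, "_beta")]] <- bb$dbeta
    cb <- conv2d_backward_cpp(blk$xin, v[[paste0("conv", i, "_W")]], bb$dx,
                              as.integer(dim(blk$xin)), as.integer(b$kernel))
    g[[paste0("conv", i, "_W")]] <- cb$dW
    g[[paste0("conv", i, "_b")]] <- cb$db
    dx <- cb$dx
  }
  g
}

#' Categorical cross-entropy
#'
#' \eqn{-\sum_i \sum_j y_{ij} \ln \hat y_{ij}}, divided by the sample count
#' under mean reduction. Predicted probabilities are clamped to
#' \eqn{[\epsilon, 1]} with \eqn{\epsilon = 10^{-12}} before the logarithm.
#'
#' @param trueLabels one-hot matrix (samples x classes).
#' @param predictedProbs probability matrix of the same shape; rows must sum
#'   to 1 within 1e-6.
#' @param reduction `"mean"` or `"sum"`.
#' @param eps clamp floor applied to the predicted probabilities.
#' @return Scalar loss.
#' @export
categoricalCrossEntropy <- function(trueLabels, predictedProbs,
                                    reduction = c("mean", "sum"),
                                    eps = 1e-12) {
  reduction <- match.arg(reduction)
  if (!all(dim(trueLabels) == dim(predictedProbs))) {
    stop("trueLabels and predictedProbs must have the same shape")
  }
  if (any(abs(rowSums(predictedProbs) - 1) > 1e-6)) {
    stop("rows of predictedProbs must sum to 1 within 1e-6")
  }
  if (any(!trueLabels %in% c(0, 1)) || any(rowSums(trueLabels) != 1)) {
    stop("trueLabels must be valid one-hot rows")
  }
  p <- pmin(pmax(predictedProbs, eps), 1)
  loss <- -sum(trueLabels * log(p))
  if (reduction == "mean") loss <- loss / nrow(trueLabels)
  loss
}

.oneHot <- function(y, k = 6) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y)] <- 1
  m
}

#' Training configuration
#'
#' @param optimizer `"sgd"` (with momentum) or `"adam"`.
#' @param learningRate positive step size.
#' @param momentum SGD momentum coefficient.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batchSize mini-batch size.
#' @param epochs number of passes over the training set.
#' @param seed RNG seed covering shuffling and dropout.
#' @param lossReduction `"mean"` (size-independent loss values) or `"sum"`.
#' @param shuffle shuffle the training order each epoch.
#' @param keepBest snapshot the parameters at the best validation accuracy.
#' @return List of class `trainConfig`.
#' @export
trainConfig <- function(optimizer = c("adam", "sgd"), learningRate = 3e-3,
                        momentum = 0.9, beta1 = 0.9, beta2 = 0.999,
                        batchSize = 32, epochs = 10, seed = 1,
                        lossReduction = c("mean", "sum"), shuffle = TRUE,
                        keepBest = TRUE) {
  optimizer <- match.arg(optimizer)
  lossReduction <- match.arg(lossReduction)
  if (learningRate < 0) stop("learningRate must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(
    list(optimizer = optimizer, learningRate = learningRate,
         momentum = momentum, beta1 = beta1, beta2 = beta2,
         batchSize = batchSize, epochs = epochs, seed = seed,
         lossReduction = lossReduction, shuffle = shuffle,
         keepBest = keepBest),
    class = "trainConfig"
  )
}

# One optimizer step, updating net@params$values in place.
.optimStep <- function(net, grads, tc, opt) {
  v <- net@params$values
  lr <- opt$lr
  if (tc$optimizer == "sgd") {
    for (nm in names(grads)) {
      opt$vel[[nm]] <- tc$momentum * opt$vel[[nm]] - lr * grads[[nm]]
      v[[nm]] <- v[[nm]] + opt$vel[[nm]]
    }
  } else {
    opt$t <- opt$t + 1
    c1 <- 1 - tc$beta1^opt$t
    c2 <- 1 - tc$beta2^opt$t
    for (nm in names(grads)) {
      opt$m[[nm]] <- tc$beta1 * opt$m[[nm]] + (1 - tc$beta1) * grads[[nm]]
      opt$v2[[nm]] <- tc$beta2 * opt$v2[[nm]] + (1 - tc$beta2) * grads[[nm]]^2
      v[[nm]] <- v[[nm]] - lr * (opt$m[[nm]] / c1) /
        (sqrt(opt$v2[[nm]] / c2) + 1e-8)
    }
  }
  net@params$values <- v
  invisible(opt)
}

.newOptState <- function(values, tc, lr) {
  zeros <- lapply(values, function(p) p * 0)
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr
  if (tc$optimizer == "sgd") opt$vel <- zeros else {
    opt$m <- zeros
    opt$v2 <- zeros
    opt$t <- 0
  }
  opt
}

.batchLoss <- function(probs, y, reduction = "mean") {
  p <- pmin(pmax(probs[cbind(y, seq_along(y))], 1e-12), 1)
  s <- -sum(log(p))
  if (reduction == "mean") s / length(y) else s
}

#' Extract model input arrays from a dataset
#'
#' @param ds a [CvmDataset].
#' @param split optional split name (`"train"`, `"validation"`, `"test"`);
#'   `NULL` takes all samples.
#' @return List with `x` (H x W x N array) and `y` (integer labels 1..6).
#' @export
modelInput <- function(ds, split = NULL) {
  keep <- if (is.null(split)) rep(TRUE, length(ds@stage)) else ds@split == split
  list(x = ds@images[, , keep, drop = FALSE], y = stageIndex(ds@stage[keep]))
}

.archList <- function(cfg) {
  list(
    filters = as.integer(cfg$convBlocks$filters),
    kernel = as.integer(cfg$convBlocks$kernel),
    pool = as.integer(cfg$convBlocks$pool),
    dropout = as.numeric(cfg$convBlocks$dropout),
    inputSide = as.integer(cfg$inputSide),
    denseWidth = as.integer(cfg$denseWidth),
    denseDropout = as.numeric(cfg$denseDropout),
    nClasses = as.integer(cfg$nClasses)
  )
}

.optList <- function(tc) {
  list(optimizer = tc$optimizer, learningRate = tc$learningRate,
       momentum = tc$momentum, beta1 = tc$beta1, beta2 = tc$beta2)
}

#' Train the network
#'
#' Mini-batch training with categorical cross-entropy. The history records
#' per-epoch training loss/accuracy (averaged over the epoch's batches, in
#' training mode) and validation loss/accuracy (evaluation mode). Training
#' runs in single precision with preallocated buffers; with a fixed seed
#' and single-threaded linear algebra, repeated runs produce identical
#' histories.
#'
#' @param net a [CvmNet] (updated in place and returned).
#' @param train,val lists with `x` (H x W x N array) and `y` (labels 1..6),
#'   e.g. from [modelInput()]; `val` may be `NULL`.
#' @param tc a [trainConfig()].
#' @return List with `net`, `history` (one row per epoch), and when
#'   validation data and `keepBest` are given, `best` (parameter snapshot,
#'   epoch, validation accuracy).
#' @export
trainModel <- function(net, train, val = NULL, tc = trainConfig()) {
  stopifnot(length(train$y) > 0)
  if (!all(train$y %in% 1:6)) stop("labels must be in 1..6")
  set.seed(as.integer(tc$seed))
  res <- cvm_train_cpp(
    train$x, as.integer(train$y),
    if (is.null(val)) NULL else val$x,
    if (is.null(val)) NULL else as.integer(val$y),
    net@params$values, net@params$state,
    .archList(net@config), .optList(tc),
    as.integer(tc$epochs), as.integer(tc$batchSize),
    isTRUE(tc$shuffle), NULL, isTRUE(tc$keepBest) && !is.null(val)
  )
  if (isTRUE(res$abort)) {
    stop(sprintf("non-finite loss at epoch %d, batch %d",
                 res$naEpoch, res$naBatch))
  }
  net@params$values <- res$values
  net@params$state <- res$state
  n <- length(train$y)
  mul <- if (tc$lossReduction == "sum") n else 1
  mulV <- if (tc$lossReduction == "sum" && !is.null(val)) length(val$y) else 1
  hist <- data.frame(
    epoch = seq_len(tc$epochs),
    train_loss = res$train_loss * mul,
    train_accuracy = res$train_accuracy,
    val_loss = res$val_loss * mulV,
    val_accuracy = res$val_accuracy
  )
  best <- NULL
  if (!is.null(res$best)) {
    best <- list(values = res$best$values, state = res$best$state,
                 epoch = res$bestEpoch, valAccuracy = res$bestAcc)
  }
  list(net = net, history = hist, best = best)
}

#' Restore the best-validation checkpoint into a model
#'
#' Replaces the model's parameters with the snapshot taken at the epoch of
#' highest validation accuracy (model selection on the validation split).
#' A no-op when the fit carries no checkpoint.
#'
#' @param net a [CvmNet].
#' @param fit result of [trainModel()].
#' @return `net`, with the checkpoint parameters installed.
#' @export
restoreBestCheckpoint <- function(net, fit) {
  if (!is.null(fit$best)) {
    net@params$values <- fit$best$values
    net@params$state <- fit$best$state
  }
  net
}

#' Predict class probabilities
#'
#' Evaluation-mode forward pass (batch-normalization running statistics, no
#' dropout). Rows sum to 1; the predicted stage is the argmax with
#' lowest-index tie-break.
#'
#' @param net a [CvmNet].
#' @param images H x W x N array (or a single H x W matrix) matching the
#'   model's input side.
#' @return N x 6 probability matrix with stage column names.
#' @export
predictProba <- function(net, images) {
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1))
  d <- dim(images)
  if (d[1] != net@config$inputSide || d[2] != net@config$inputSide) {
    stop(sprintf("images are %dx%d but the model expects %dx%d",
                 d[1], d[2], net@config$inputSide, net@config$inputSide))
  }
  n <- d[3]
  out <- cvm_predict_cpp(images, as.integer(n), net@params$values,
                         net@params$state, .archList(net@config), 128L)
  colnames(out) <- stageLevels()[seq_len(net@config$nClasses)]
  out
}

#' Predict stage labels
#' @inheritParams predictProba
#' @return Ordered factor of stages (argmax, lowest index wins ties).
#' @export
predictStage <- function(net, images) {
  p <- predictProba(net, images)
  asStage(max.col(p, ties.method = "first"))
}

#' Exponential learning-rate range test
#'
#' Trains for `nSteps` batch updates while increasing the learning rate
#' exponentially from `lrBounds[1]` to `lrBounds[2]` (step k uses
#' \eqn{lr_k = low \cdot (high/low)^{k/(n-1)}}), recording the batch loss at
#' each update. The model parameters are restored to their pre-test values
#' afterwards.
#'
#' @param net a [CvmNet].
#' @param train list with `x` and `y`; batches cycle through it in order.
#' @param lrBounds `c(low, high)` with `0 < low < high`.
#' @param nSteps number of batch updates, `>= 2`.
#' @param batchSize batch size.
#' @param tc optimizer settings (the learning rate field is ignored).
#' @return data.frame of class `lrRangeResult` with columns `step`,
#'   `learning_rate`, `loss`.
#' @export
lrRangeTest <- function(net, train, lrBounds = c(0.1, 10), nSteps = 50,
                        batchSize = 32, tc = trainConfig(optimizer = "sgd")) {
  if (nSteps < 2) stop("nSteps must be >= 2")
  if (!(lrBounds[1] > 0 && lrBounds[1] < lrBounds[2])) {
    stop("lrBounds must satisfy 0 < low < high")
  }
  lrs <- lrBounds[1] * (lrBounds[2] / lrBounds[1])^((seq_len(nSteps) - 1) /
                                                      (nSteps - 1))
  # the engine works on parameter copies, so the model itself is untouched
  res <- cvm_train_cpp(
    train$x, as.integer(train$y), NULL, NULL,
    net@params$values, net@params$state,
    .archList(net@config), .optList(tc),
    1L, as.integer(batchSize), FALSE, lrs, FALSE
  )
  structure(
    data.frame(step = seq_len(nSteps), learning_rate = lrs,
               loss = res$stepLosses),
    class = c("lrRangeResult", "data.frame")
  )
}

#' Select a learning rate from a range-test curve
#'
#' Smooths the loss curve with a centered moving average and returns the
#' learning rate at the steepest loss decrease (most negative finite
#' difference). If the loss never decreases, a warning is raised and the
#' lower bound is returned.
#'
#' @param result an [lrRangeTest()] result.
#' @param window moving-average window (odd; partial at the edges).
#' @return Selected learning rate (scalar).
#' @export
selectLR <- function(result, window = 5) {
  stopifnot(nrow(result) >= 1)
  x <- result$loss
  n <- length(x)
  half <- floor(window / 2)
  sm <- vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  if (n == 1) return(result$learning_rate[1])
  d <- diff(sm)
  k <- which.min(d)
  if (d[k] >= 0) {
    warning("loss never decreases over the tested range; returning the lower bound")
    return(result$learning_rate[1])
  }
  result$learning_rate[k + 1]
}

#' Confidence-thresholded self-training update
#'
#' Moves pool samples that the model classifies correctly with maximum
#' predicted probability at or above `probThreshold` into the training set,
#' keeping the two sets disjoint.
#'
#' @param net a [CvmNet].
#' @param train,pool lists with `x` and `y` (pool labels are required so
#'   correctness is checkable).
#' @param probThreshold confidence threshold in (0, 1].
#' @return List with the augmented `train`, the reduced `pool`, and a
#'   `log` data.frame (pool index, predicted stage, label, probability,
#'   moved flag).
#' @export
selfTrainingUpdate <- function(net, train, pool, probThreshold = 0.99) {
  if (!(probThreshold > 0 && probThreshold <= 1)) {
    stop("probThreshold must be in (0, 1]")
  }
  n <- length(pool$y)
  if (n == 0) {
    message("self-training: pool is empty, nothing to move")
    return(list(train = train, pool = pool,
                log = data.frame(index = integer(), predicted = integer(),
                                 label = integer(), probability = numeric(),
                                 moved = logical())))
  }
  p <- predictProba(net, pool$x)
  pred <- max.col(p, ties.method = "first")
  maxp <- p[cbind(seq_len(n), pred)]
  moved <- pred == pool$y & maxp >= probThreshold
  log <- data.frame(index = seq_len(n), predicted = pred, label = pool$y,
                    probability = maxp, moved = moved)
  if (any(moved)) {
    train <- list(
      x = .bindImages(train$x, pool$x[, , moved, drop = FALSE]),
      y = c(train$y, pool$y[moved])
    )
    pool <- list(x = pool$x[, , !moved, drop = FALSE], y = pool$y[!moved])
  }
  list(train = train, pool = pool, log = log)
}

.bindImages <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the parameter values, running
#' statistics and configuration; a sidecar JSON next to it records the
#' configuration and seed for reproducibility.
#'
#' @param net a [CvmNet].
#' @param path checkpoint path (`.rds`).
#' @param meta optional extra metadata for the sidecar (e.g. the training
#'   configuration and seed).
#' @return `path`, invisibly.
#' @export
saveModel <- function(net, path, meta = list()) {
  saveRDS(list(config = net@config, values = net@params$values,
               state = net@params$state), path)
  side <- sub("\\.rds$", ".json", path)
  if (side == path) side <- paste0(path, ".json")
  cfg <- net@config
  cfg$convBlocks <- as.list(cfg$convBlocks)
  jsonlite::write_json(c(list(modelConfig = cfg), meta), side,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  env <- new.env(parent = emptyenv())
  env$values <- x$values
  env$state <- x$state
  new("CvmNet", config = x$config, params = env)
}
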