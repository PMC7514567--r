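# Evaluation artifacts: 6x6 confusion matrix, per-class
# precision/recall/F1/support report, one-vs-rest per-class accuracy, and
# the per-class probability grids.

#' Round half away from zero
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values (0.675 -> 0.68 at 2 digits).
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  # small epsilon compensates binary representation of decimal halves
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Confusion matrix for the six stages
#'
#' @param trueStages,predictedStages equal-length stage vectors (integers
#'   1..6 or labels CS1..CS6).
#' @return 6 x 6 integer matrix, rows = true stage, columns = predicted
#'   stage, with stage dimnames.
#' @export
confusionMatrix6 <- function(trueStages, predictedStages) {
  t6 <- asStage(trueStages)
  p6 <- asStage(predictedStages)
  if (length(t6) != length(p6)) {
    stop("true and predicted stage sequences must have equal length")
  }
  m <- table(true = t6, predicted = p6)
  cm <- matrix(as.integer(m), 6, 6,
               dimnames = list(true = stageLevels(), predicted = stageLevels()))
  cm
}

.checkCM <- function(cm) {
  if (!is.matrix(cm) || any(dim(cm) != 6) || any(cm < 0)) {
    stop("cm must be a 6 x 6 matrix of non-negative counts")
  }
  cm
}

#' Per-class classification report
#'
#' Precision (column-wise), recall (row-wise), F1 (harmonic mean) and
#' support per class, plus overall accuracy (trace over total). Zero
#' denominators yield 0 with a flag. Values are reported at full precision
#' with 2-decimal rounded companions (half away from zero).
#'
#' @param cm confusion matrix as from [confusionMatrix6()].
#' @return Object of class `cvmClassReport`: list with `perClass`
#'   data.frame, `accuracy`, `total` and `zeroDivision` flag.
#' @export
classificationReport <- function(cm) {
  cm <- .checkCM(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  tp <- diag(cm)
  prec <- ifelse(cs > 0, tp / cs, 0)
  rec <- ifelse(rs > 0, tp / rs, 0)
  zd <- any(cs == 0) || any(rs == 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  total <- sum(cm)
  acc <- if (total > 0) sum(tp) / total else 0
  perClass <- data.frame(
    class = stageLevels(),
    precision = as.numeric(prec), recall = as.numeric(rec),
    f1 = as.numeric(f1), support = as.numeric(rs),
    precision_2dp = roundHalfUp(as.numeric(prec)),
    recall_2dp = roundHalfUp(as.numeric(rec)),
    f1_2dp = roundHalfUp(as.numeric(f1)),
    row.names = stageLevels()
  )
  structure(
    list(perClass = perClass, accuracy = acc, total = total,
         zeroDivision = zd),
    class = "cvmClassReport"
  )
}

#' @export
print.cvmClassReport <- function(x, ...) {
  cat("Classification report\n")
  df <- x$perClass
  cat(sprintf("%-6s %9s %9s %9s %9s\n", "", "precision", "recall", "f1-score",
              "support"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("%-6s %9.2f %9.2f %9.2f %9d\n", df$class[i],
                df$precision_2dp[i], df$recall_2dp[i], df$f1_2dp[i],
                as.integer(df$support[i])))
  }
  cat(sprintf("accuracy: %.2f on %d samples\n", roundHalfUp(x$accuracy),
              x$total))
  invisible(x)
}

#' One-vs-rest per-class accuracy
#'
#' Collapses the 6-class confusion matrix to class-j-versus-rest and returns
#' (TP + TN) / total for each class; TN counts samples neither true nor
#' predicted as class j.
#'
#' @param cm confusion matrix as from [confusionMatrix6()].
#' @return Named numeric vector of six accuracies.
#' @export
perClassAccuracy <- function(cm) {
  cm <- .checkCM(cm)
  total <- sum(cm)
  out <- vapply(1:6, function(j) {
    tp <- cm[j, j]
    fn <- sum(cm[j, ]) - tp
    fp <- sum(cm[, j]) - tp
    tn <- total - tp - fn - fp
    if (total > 0) (tp + tn) / total else 0
  }, numeric(1))
  names(out) <- stageLevels()
  out
}

#' Per-class probability grids
#'
#' Groups test samples by true class (in input order) and returns, for each
#' true class, a 6 x n raster whose cell (j, i) is the predicted probability
#' of class j for the i-th sample of that class; each column sums to 1.
#'
#' @param probs N x 6 probability matrix (one row per sample).
#' @param trueStages length-N stage vector.
#' @return Named list of six 6 x n matrices (class `cvmProbabilityGrid`).
#'   A class absent from `trueStages` yields an empty raster with a warning.
#' @export
probabilityGrid <- function(probs, trueStages) {
  t6 <- asStage(trueStages)
  if (nrow(probs) != length(t6)) {
    stop("probs must have one row per sample")
  }
  out <- lapply(1:6, function(s) {
    keep <- which(as.integer(t6) == s)
    if (length(keep) == 0) {
      warning("no samples with true stage ", stageLevels()[s])
      return(matrix(numeric(0), 6, 0))
    }
    t(probs[keep, , drop = FALSE])
  })
  names(out) <- stageLevels()
  structure(out, class = "cvmProbabilityGrid")
}

#' Write probability grids as images and CSV
#'
#' Each class raster is written as a grayscale PNG heatmap (rows upscaled by
#' `scale` for visibility) plus a raw CSV of the probabilities.
#'
#' @param grid a [probabilityGrid()] result.
#' @param dir output directory (created if needed).
#' @param scale integer pixel upscaling factor.
#' @return Character vector of the written PNG paths, invisibly.
#' @export
writeProbabilityGrid <- function(grid, dir, scale = 8) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(grid)) {
    g <- grid[[nm]]
    utils::write.csv(g, file.path(dir, paste0("probgrid_", nm, ".csv")),
                     row.names = FALSE)
    if (ncol(g) == 0) next
    big <- g[rep(seq_len(nrow(g)), each = scale),
             rep(seq_len(ncol(g)), each = scale), drop = FALSE]
    p <- file.path(dir, paste0("probgrid_", nm, ".png"))
    writeGrayPNG(big, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Overall accuracy from a confusion matrix
#' @param cm confusion matrix.
#' @return Scalar trace / total.
#' @export
overallAccuracy <- function(cm) {
  cm <- .checkCM(cm)
  sum(diag(cm)) / sum(cm)
}

#' Write a confusion matrix as CSV
#' @param cm confusion matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConfusionCSV <- function(cm, path) {
  utils::write.csv(as.data.frame(cm), path, row.names = TRUE)
  invisible(path)
}
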