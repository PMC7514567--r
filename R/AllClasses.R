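#' @useDynLib cvmStager, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Ordered CVM stage labels
#'
#' The six cervical vertebral maturation stages, CS1 (least mature, about two
#' years before the mandibular growth peak) through CS6 (fully matured
#' vertebral bodies).
#'
#' @return Character vector of the six stage names in order.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() paste0("CS", 1:6)

#' Coerce stage labels to an ordered factor
#'
#' Accepts integers 1..6 or character labels "CS1".."CS6".
#'
#' @param x integer or character vector of stages.
#' @return Ordered factor with levels CS1 < ... < CS6.
#' @export
asStage <- function(x) {
  lev <- stageLevels()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(!x %in% 1:6)) stop("stage indices must be in 1..6")
    x <- lev[x]
  }
  if (any(!x %in% lev)) stop("stage labels must be CS1..CS6")
  factor(x, levels = lev, ordered = TRUE)
}

#' Integer index of stage labels
#' @param x stages in any form accepted by [asStage()].
#' @return Integer vector in 1..6.
#' @export
stageIndex <- function(x) as.integer(asStage(x))

#' @rdname VertebraGeometry-class
#' @export
setClass("VertebraGeometry",
  representation(
    landmarks = "matrix",
    concavityDepth = "numeric",
    posteriorHeight = "numeric",
    anteriorHeight = "numeric",
    baseLength = "numeric"
  )
)

setValidity("VertebraGeometry", function(object) {
  lm <- object@landmarks
  msgs <- character()
  need <- c("Cla", "Clp", "Cm", "Cua", "Cup")
  if (!all(need %in% rownames(lm)) || ncol(lm) != 2) {
    return("landmarks must be a 5 x 2 matrix with rows Cla, Clp, Cm, Cua, Cup")
  }
  if (all(lm["Cla", ] == lm["Clp", ])) msgs <- c(msgs, "Cla and Clp coincide")
  if (lm["Cla", 1] <= lm["Clp", 1]) {
    msgs <- c(msgs, "anterior landmarks must lie right (larger x) of posterior ones")
  }
  if (lm["Cm", 1] < min(lm["Clp", 1], lm["Cla", 1]) ||
      lm["Cm", 1] > max(lm["Clp", 1], lm["Cla", 1])) {
    msgs <- c(msgs, "Cm must lie horizontally between Clp and Cla")
  }
  if (object@concavityDepth < 0) msgs <- c(msgs, "concavityDepth must be >= 0")
  if (object@posteriorHeight <= 0 || object@anteriorHeight <= 0 ||
      object@baseLength <= 0) {
    msgs <- c(msgs, "heights and base length must be strictly positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Vertebral body geometry
#'
#' Landmark coordinates and summary dimensions of one vertebral body.
#' Coordinates are 0-based pixels with the origin at the top-left corner,
#' x rightward and y downward, so the lower border has the larger y.
#'
#' @slot landmarks 5 x 2 matrix (rows Cla, Clp, Cm, Cua, Cup; columns x, y).
#' @slot concavityDepth depth (px) of the lower-border dip at Cm.
#' @slot posteriorHeight,anteriorHeight,baseLength body dimensions in px.
#' @name VertebraGeometry-class
#' @aliases VertebraGeometry
NULL

setMethod("show", "VertebraGeometry", function(object) {
  cat(sprintf(
    "VertebraGeometry: base %.1f px, heights %.1f/%.1f px (post/ant), concavity %.2f px\n",
    object@baseLength, object@posteriorHeight, object@anteriorHeight,
    object@concavityDepth
  ))
})

#' @rdname GeneratorConfig-class
#' @export
setClass("GeneratorConfig",
  representation(
    imageSize = "numeric",
    nPerClass = "numeric",
    noiseSd = "numeric",
    rotationJitter = "numeric",
    scaleJitter = "numeric",
    backgroundGradient = "numeric",
    brightnessJitter = "numeric",
    contrastRange = "numeric",
    foreground = "numeric",
    background = "numeric",
    borderValue = "numeric",
    seed = "numeric",
    onOutOfBounds = "character",
    stageTable = "data.frame"
  )
)

.stageTableCols <- c(
  "conc2_lo", "conc2_hi", "conc3_lo", "conc3_hi", "conc4_lo", "conc4_hi",
  "taper_lo", "taper_hi", "len3_lo", "len3_hi", "len4_lo", "len4_hi",
  "gap_lo", "gap_hi"
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  if (object@imageSize < 32) msgs <- c(msgs, "imageSize must be >= 32")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@rotationJitter < 0) msgs <- c(msgs, "rotationJitter must be >= 0")
  if (object@scaleJitter < 0) msgs <- c(msgs, "scaleJitter must be >= 0")
  if (!object@onOutOfBounds %in% c("regenerate", "fail")) {
    msgs <- c(msgs, "onOutOfBounds must be 'regenerate' or 'fail'")
  }
  st <- object@stageTable
  if (nrow(st) != 6 || !all(.stageTableCols %in% names(st))) {
    return(paste(
      "stageTable must have 6 rows (CS1..CS6) and columns",
      paste(.stageTableCols, collapse = ", ")
    ))
  }
  lo <- st[, grep("_lo$", names(st))]
  hi <- st[, grep("_hi$", names(st))]
  if (any(as.matrix(hi) < as.matrix(lo))) {
    msgs <- c(msgs, "stageTable ranges must have lo <= hi")
  }
  # Stage progression constraints: mean concavity depth across the three
  # vertebrae must be non-decreasing CS1 -> CS6, and the base/height aspect
  # ratio must not increase from CS4 to CS6.
  meanDepth <- rowMeans((st[, c("conc2_lo", "conc3_lo", "conc4_lo")] +
    st[, c("conc2_hi", "conc3_hi", "conc4_hi")]) / 2)
  if (any(diff(meanDepth) < -1e-9)) {
    msgs <- c(msgs, "mean concavity depth must be non-decreasing across stages")
  }
  meanLen <- ((st$len3_lo + st$len3_hi) + (st$len4_lo + st$len4_hi)) / 4
  if (any(diff(meanLen[4:6]) > 1e-9)) {
    msgs <- c(msgs, "body aspect ratio must be non-increasing from CS4 to CS6")
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic generator configuration
#'
#' Controls the synthetic vertebra-image generator: raster size, per-class
#' counts, noise and jitter levels, rendering intensities, and the per-stage
#' morphology parameter table (concavity depths, tapering and lengthening
#' ratio ranges, inter-body gaps) expressed at a 256-px reference scale.
#'
#' @name GeneratorConfig-class
#' @aliases GeneratorConfig
NULL

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    paste0(
      "GeneratorConfig: %d x %d px, %d per class, noise sd %.3f\n",
      "  jitter: rotation %.1f deg, scale %.3f; background gradient %.2f\n",
      "  intensity jitter: brightness %.2f, contrast [%.2f, %.2f]; seed %d\n"
    ),
    object@imageSize, object@imageSize, object@nPerClass, object@noiseSd,
    object@rotationJitter, object@scaleJitter, object@backgroundGradient,
    object@brightnessJitter, object@contrastRange[1], object@contrastRange[2],
    as.integer(object@seed)
  ))
})

#' @rdname SyntheticSample-class
#' @export
setClass("SyntheticSample",
  representation(
    image = "matrix",
    stage = "integer",
    geometry = "list",
    provenance = "list"
  )
)

setValidity("SyntheticSample", function(object) {
  msgs <- character()
  if (!object@stage %in% 1:6) msgs <- c(msgs, "stage must be in 1..6")
  if (!all(c("C2", "C3", "C4") %in% names(object@geometry))) {
    msgs <- c(msgs, "geometry must contain C2, C3, C4")
  }
  n <- dim(object@image)
  for (g in object@geometry) {
    lm <- g@landmarks
    if (any(lm[, 1] < 0) || any(lm[, 1] > n[2] - 1) ||
        any(lm[, 2] < 0) || any(lm[, 2] > n[1] - 1)) {
      msgs <- c(msgs, "landmarks must lie inside the image bounds")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' One rendered synthetic sample
#'
#' A rendered grayscale image (values in [0, 1]) together with the stage that
#' generated it and the per-vertebra geometry after jitter.
#'
#' @name SyntheticSample-class
#' @aliases SyntheticSample
NULL

setMethod("show", "SyntheticSample", function(object) {
  cat(sprintf(
    "SyntheticSample: %d x %d px, stage %s\n",
    nrow(object@image), ncol(object@image), stageLevels()[object@stage]
  ))
})

#' @rdname CvmDataset-class
#' @export
setClass("CvmDataset",
  representation(
    images = "array",
    stage = "factor",
    split = "factor",
    landmarks = "matrix",
    manifest = "data.frame",
    config = "GeneratorConfig"
  )
)

setValidity("CvmDataset", function(object) {
  n <- dim(object@images)[3]
  if (length(object@stage) != n || length(object@split) != n ||
      nrow(object@landmarks) != n || nrow(object@manifest) != n) {
    return("images, stage, split, landmarks and manifest must agree in length")
  }
  TRUE
})

#' In-memory labeled image dataset
#'
#' Images stacked as an H x W x N array with per-sample stage labels,
#' train/validation/test split assignment, and ground-truth landmark
#' coordinates (one row of 30 values per sample: 3 vertebrae x 5 landmarks
#' x 2 coordinates).
#'
#' @name CvmDataset-class
#' @aliases CvmDataset
NULL

setMethod("show", "CvmDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf("CvmDataset: %d images of %d x %d px\n", d[3], d[1], d[2]))
  print(table(stage = object@stage, split = object@split))
})

#' @rdname CvmNet-class
#' @export
setClass("CvmNet",
  representation(config = "list", params = "environment")
)

#' Compact convolutional staging network
#'
#' A handle to the compact CNN: five (by default) blocks of convolution,
#' batch normalization, ReLU, max pooling and dropout, followed by one dense
#' block and a 6-way softmax. Parameters live in an environment so training
#' updates them in place.
#'
#' @name CvmNet-class
#' @aliases CvmNet
NULL

setMethod("show", "CvmNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CvmNet: input %dx%d, %d conv blocks (filters %s), dense %d -> %d classes\n",
    cfg$inputSide, cfg$inputSide, nrow(cfg$convBlocks),
    paste(cfg$convBlocks$filters, collapse = "/"),
    cfg$denseWidth, cfg$nClasses
  ))
  cat(sprintf("  %d trainable parameters\n", nParams(object)))
})

#' Dataset accessors
#'
#' @param x a [CvmDataset].
#' @return `imageStack` returns the H x W x N image array, `stages` the stage
#'   factor, `dataSplit` the split factor, `landmarkTable` the landmark
#'   coordinate matrix, and `manifest` the manifest data frame.
#' @name dataset-accessors
#' @aliases imageStack stages dataSplit landmarkTable manifest
NULL

#' @rdname dataset-accessors
#' @export
setGeneric("imageStack", function(x) standardGeneric("imageStack"))
#' @rdname dataset-accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname dataset-accessors
#' @export
setGeneric("dataSplit", function(x) standardGeneric("dataSplit"))
#' @rdname dataset-accessors
#' @export
setGeneric("landmarkTable", function(x) standardGeneric("landmarkTable"))
#' @rdname dataset-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname dataset-accessors
setMethod("imageStack", "CvmDataset", function(x) x@images)
#' @rdname dataset-accessors
setMethod("stages", "CvmDataset", function(x) x@stage)
#' @rdname dataset-accessors
setMethod("dataSplit", "CvmDataset", function(x) x@split)
#' @rdname dataset-accessors
setMethod("landmarkTable", "CvmDataset", function(x) x@landmarks)
#' @rdname dataset-accessors
setMethod("manifest", "CvmDataset", function(x) x@manifest)

#' Number of trainable parameters
#' @param x a [CvmNet].
#' @return Integer parameter count.
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))

#' @rdname nParams
setMethod("nParams", "CvmNet", function(x) {
  sum(vapply(x@params$values, length, integer(1)))
})
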