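# Image preprocessing operators: cropping, resizing, Sobel edge magnitude,
# and sliding-window mean / median / entropy filters, composable into an
# ordered pipeline with a provenance record.

#' Read a grayscale PNG
#'
#' Multi-channel files are averaged to a single channel. Values are returned
#' on the [0, 1] scale regardless of the file's bit depth.
#'
#' @param path PNG file path.
#' @return Numeric matrix (rows = image rows).
#' @export
readGrayPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  x
}

#' Write a grayscale PNG (8-bit)
#' @param img numeric matrix with values in [0, 1] (clamped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGrayPNG <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Crop a rectangular region
#'
#' @param img numeric matrix.
#' @param roi `c(x, y, width, height)`: 1-based column (`x`) and row (`y`) of
#'   the top-left corner plus the region size.
#' @return The cropped matrix; pixel values are copied unchanged.
#' @export
cropImage <- function(img, roi) {
  roi <- as.integer(round(roi))
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x < 1 || y < 1 || w < 1 || h < 1 ||
      x + w - 1 > ncol(img) || y + h - 1 > nrow(img)) {
    stop("crop ROI outside image bounds")
  }
  img[y:(y + h - 1), x:(x + w - 1), drop = FALSE]
}

#' Centered square crop
#' @param img numeric matrix.
#' @param side side of the square in pixels.
#' @return Cropped matrix.
#' @export
cropCenter <- function(img, side) {
  x <- floor((ncol(img) - side) / 2) + 1
  y <- floor((nrow(img) - side) / 2) + 1
  cropImage(img, c(x, y, side, side))
}

#' Resize an image
#'
#' @param img numeric matrix.
#' @param side output side in pixels (square output), `>= 8`.
#' @param method `"area"` (area-weighted average, the default for
#'   downscaling radiographs without aliasing), `"bilinear"`, or
#'   `"nearest"`.
#' @return `side` x `side` matrix.
#' @export
resizeImage <- function(img, side, method = c("area", "bilinear", "nearest")) {
  method <- match.arg(method)
  if (side < 8) stop("resize side must be >= 8")
  m <- match(method, c("nearest", "bilinear", "area")) - 1L
  resize_cpp(img, as.integer(side), as.integer(side), m)
}

#' Sliding-window specification
#'
#' @param shape `"square"` (odd side length) or `"disk"` (radius).
#' @param size side in pixels for squares, radius for disks.
#' @param border `"reflect"` (mirror) or `"constant"`.
#' @param value fill value for the constant border policy.
#' @return Object of class `windowSpec`.
#' @export
windowSpec <- function(shape = c("square", "disk"), size = 3,
                       border = c("reflect", "constant"), value = 0) {
  shape <- match.arg(shape)
  border <- match.arg(border)
  if (shape == "square") {
    if (size < 1 || size %% 2 == 0) stop("square window side must be odd and >= 1")
  } else if (size < 1) stop("disk radius must be >= 1")
  structure(list(shape = shape, size = size, border = border, value = value),
            class = "windowSpec")
}

.windowOffsets <- function(window) {
  if (window$shape == "square") {
    h <- (window$size - 1) / 2
    g <- expand.grid(dr = -h:h, dc = -h:h)
  } else {
    r <- window$size
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  }
  as.matrix(g)
}

.localFilter <- function(img, window, op, bins = 0L, range = c(0, 1),
                         base = exp(1)) {
  stopifnot(inherits(window, "windowSpec"))
  off <- .windowOffsets(window)
  if (op == 2L && nrow(off) < 2) {
    stop("entropy window must cover at least 2 pixels")
  }
  local_filter_cpp(
    img, off, as.integer(op), as.integer(bins), range[1], range[2],
    if (window$border == "reflect") 0L else 1L, window$value, base
  )
}

#' Local mean filter
#' @param img numeric matrix.
#' @param window a [windowSpec()].
#' @return Filtered matrix of the same size.
#' @export
localMean <- function(img, window = windowSpec("square", 3)) {
  .localFilter(img, window, 0L)
}

#' Local median filter
#' @inheritParams localMean
#' @return Filtered matrix of the same size.
#' @export
localMedian <- function(img, window = windowSpec("square", 3)) {
  .localFilter(img, window, 1L)
}

#' Local entropy filter
#'
#' Each output pixel is the Shannon entropy \eqn{-\sum_n p_n \ln p_n} of the
#' histogram (with `bins` equal-width bins over `range`) of the intensities
#' in the window centered there. The output lies in
#' \eqn{[0, \log_b(\mathrm{bins})]}; a constant neighborhood gives 0 and a
#' neighborhood spread uniformly over the occupied bins gives the maximum.
#' Because the statistic depends only on the local distribution of gray
#' levels, not their absolute values, it highlights structural complexity
#' (contours, texture boundaries) while suppressing smooth intensity trends.
#'
#' @param img numeric matrix with values inside `range` (clamped otherwise).
#' @param window a [windowSpec()] covering at least 2 pixels.
#' @param bins histogram bin count, `>= 2`.
#' @param base logarithm base; natural log by default.
#' @param range declared intensity range of the input.
#' @param normalize if `TRUE`, divide by `log(bins, base)` so values lie in
#'   [0, 1] (convenient as classifier input).
#' @return Filtered matrix of the same size.
#' @export
localEntropy <- function(img, window = windowSpec("disk", 5), bins = 256,
                         base = exp(1), range = c(0, 1), normalize = FALSE) {
  if (bins < 2) stop("bins must be >= 2")
  out <- .localFilter(img, window, 2L, bins = bins, range = range, base = base)
  if (normalize) out <- out / log(bins, base = base)
  out
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel kernels in both axes with mirrored borders; returns the
#' non-negative gradient magnitude, enhancing the contours of the image.
#'
#' @param img numeric matrix, at least 3 x 3.
#' @return Matrix of the same size.
#' @export
sobelMagnitude <- function(img) {
  if (nrow(img) < 3 || ncol(img) < 3) stop("image must be at least 3 x 3")
  sobel_cpp(img)
}

.knownOps <- c("crop", "cropCenter", "resize", "sobel", "mean", "median",
               "entropy", "rescale")

#' Build a preprocessing pipeline specification
#'
#' Each step is a list with an `op` field and its parameters:
#' \describe{
#'   \item{crop}{`roi = c(x, y, w, h)`}
#'   \item{cropCenter}{`side`}
#'   \item{resize}{`side`, optional `method`}
#'   \item{sobel}{(none)}
#'   \item{mean, median}{optional `window` (list with shape/size/border)}
#'   \item{entropy}{optional `window`, `bins`, `normalize`}
#'   \item{rescale}{min-max rescale to [0, 1]}
#' }
#'
#' @param ... step lists, applied in order.
#' @return Object of class `preprocSpec`.
#' @export
preprocSpec <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.null(steps[[1]]$op) && is.list(steps[[1]])) {
    steps <- steps[[1]]
  }
  for (s in steps) {
    if (is.null(s$op) || !s$op %in% .knownOps) {
      stop("unknown preprocessing op: ", if (is.null(s$op)) "<missing>" else s$op)
    }
  }
  structure(steps, class = "preprocSpec")
}

#' Read a pipeline specification from YAML
#' @param path YAML file containing a `steps` list (or a bare list of steps).
#' @return A `preprocSpec`.
#' @export
readPreprocSpec <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$steps)) y <- y$steps
  preprocSpec(y)
}

.stepWindow <- function(s, default = windowSpec("square", 3)) {
  if (is.null(s$window)) return(default)
  w <- s$window
  if (inherits(w, "windowSpec")) return(w)
  windowSpec(
    shape = if (is.null(w$shape)) "square" else w$shape,
    size = if (is.null(w$size)) 3 else w$size,
    border = if (is.null(w$border)) "reflect" else w$border,
    value = if (is.null(w$value)) 0 else w$value
  )
}

.applyStep <- function(img, s) {
  switch(s$op,
    crop = cropImage(img, s$roi),
    cropCenter = cropCenter(img, s$side),
    resize = resizeImage(img, s$side,
                         method = if (is.null(s$method)) "area" else s$method),
    sobel = sobelMagnitude(img),
    mean = localMean(img, .stepWindow(s)),
    median = localMedian(img, .stepWindow(s)),
    entropy = localEntropy(
      img, .stepWindow(s, windowSpec("disk", 5)),
      bins = if (is.null(s$bins)) 256 else s$bins,
      base = if (is.null(s$base)) exp(1) else s$base,
      range = if (is.null(s$range)) c(0, 1) else s$range,
      normalize = isTRUE(s$normalize)
    ),
    rescale = {
      rng <- range(img)
      if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    }
  )
}

#' Apply an ordered preprocessing pipeline
#'
#' Steps are applied in order; the returned image carries a `provenance`
#' attribute recording the applied steps. A failure names the failing step.
#'
#' @param img numeric matrix.
#' @param spec a [preprocSpec()] (an empty spec is the identity).
#' @return Processed matrix with a `provenance` attribute.
#' @export
applyPipeline <- function(img, spec) {
  if (!inherits(spec, "preprocSpec")) spec <- preprocSpec(spec)
  prov <- list()
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    img <- tryCatch(
      .applyStep(img, s),
      error = function(e) {
        stop(sprintf("pipeline step %d (%s) failed: %s", i, s$op,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    prov[[i]] <- s
  }
  attr(img, "provenance") <- prov
  img
}

#' Preprocess every image of a dataset
#'
#' @param ds a [CvmDataset].
#' @param spec a [preprocSpec()].
#' @return A new [CvmDataset] whose image stack holds the processed images
#'   (landmarks keep the generation-scale coordinates).
#' @export
preprocessDataset <- function(ds, spec) {
  n <- dim(ds@images)[3]
  first <- applyPipeline(ds@images[, , 1], spec)
  out <- array(0, dim = c(nrow(first), ncol(first), n))
  out[, , 1] <- first
  if (n > 1) {
    for (i in 2:n) out[, , i] <- applyPipeline(ds@images[, , i], spec)
  }
  ds@images <- out
  validObject(ds)
  ds
}
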