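# Landmark-based cephalometric measurements and the six-stage morphological
# decision cascade.

#' Construct a landmark set
#'
#' The five cephalometric points of one vertebral body in pixel coordinates
#' (y increasing downward): Cla / Clp are the lower anterior / posterior
#' corners, Cm the lower-border midpoint, Cua / Cup the upper anterior /
#' posterior corners. Anterior points have larger x than posterior ones.
#'
#' @param Cla,Clp,Cm,Cua,Cup length-2 numeric vectors (x, y).
#' @return 5 x 2 matrix with the landmark names as row names.
#' @export
landmarkSet <- function(Cla, Clp, Cm, Cua, Cup) {
  m <- rbind(Cla = Cla, Clp = Clp, Cm = Cm, Cua = Cua, Cup = Cup)
  colnames(m) <- c("x", "y")
  if (all(m["Cla", ] == m["Clp", ])) stop("Cla and Clp must differ")
  if (m["Cla", 1] <= m["Clp", 1] || m["Cua", 1] <= m["Cup", 1]) {
    stop("anterior landmarks must lie right (larger x) of posterior ones")
  }
  if (m["Cm", 1] < min(m["Clp", 1], m["Cla", 1]) ||
      m["Cm", 1] > max(m["Clp", 1], m["Cla", 1])) {
    stop("Cm must lie horizontally between Clp and Cla")
  }
  m
}

.asLandmarks <- function(lm) {
  if (!is.matrix(lm) || ncol(lm) != 2 ||
      !all(c("Cla", "Clp", "Cm", "Cua", "Cup") %in% rownames(lm))) {
    stop("landmarks must be a 5 x 2 matrix with rows Cla, Clp, Cm, Cua, Cup")
  }
  lm
}

#' Lower-border concavity depth
#'
#' Perpendicular distance of the lower-border midpoint Cm from the chord
#' joining the posterior and anterior lower points (Clp-Cla), positive when
#' Cm lies below the chord (deeper y) and clamped to 0 when on or above it.
#'
#' @param lm landmark matrix as from [landmarkSet()].
#' @return Non-negative depth in pixels.
#' @export
concavityDepth <- function(lm) {
  lm <- .asLandmarks(lm)
  v <- lm["Cla", ] - lm["Clp", ]
  w <- lm["Cm", ] - lm["Clp", ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("Cla and Clp coincide")
  # with y downward and Cla right of Clp, a positive cross product means Cm
  # lies below the chord
  max(0, (v[1] * w[2] - v[2] * w[1]) / nv)
}

#' Superior-border tapering ratio
#'
#' Ratio of posterior to anterior body heights, |Cup-Clp| / |Cua-Cla|
#' (Euclidean lengths, hence rotation-invariant). Values above 1 indicate a
#' superior border sloping down from posterior to anterior, the hallmark of
#' the early stages.
#'
#' @inheritParams concavityDepth
#' @return Positive dimensionless ratio.
#' @export
taperingRatio <- function(lm) {
  lm <- .asLandmarks(lm)
  ant <- sqrt(sum((lm["Cua", ] - lm["Cla", ])^2))
  if (ant == 0) stop("anterior height is zero")
  sqrt(sum((lm["Cup", ] - lm["Clp", ])^2)) / ant
}

#' Body lengthening ratio
#'
#' Ratio of base length to anterior body height, |Clp-Cla| / |Cua-Cla|.
#' Distinguishes horizontal-rectangular (ratio > 1), square (about 1) and
#' vertical-rectangular bodies (ratio < 1, "higher than wide").
#'
#' @inheritParams concavityDepth
#' @return Positive dimensionless ratio.
#' @export
lengtheningRatio <- function(lm) {
  lm <- .asLandmarks(lm)
  ant <- sqrt(sum((lm["Cua", ] - lm["Cla", ])^2))
  if (ant == 0) stop("anterior height is zero")
  sqrt(sum((lm["Clp", ] - lm["Cla", ])^2)) / ant
}

#' All three cephalometric measurements
#'
#' @inheritParams concavityDepth
#' @return List with `concavity`, `taper` and `lengthening`.
#' @export
cephFeatures <- function(lm) {
  list(
    concavity = concavityDepth(lm),
    taper = taperingRatio(lm),
    lengthening = lengtheningRatio(lm)
  )
}

#' Stage decision rule configuration
#'
#' Quantizes the qualitative six-stage morphology into thresholds. The flat
#' threshold is 1 px at a 256-px render scale and scales linearly with the
#' image size; a concavity counts as "deepened" at `deepenedFactor` times
#' the flat threshold.
#'
#' @param imageSize render scale the landmarks are expressed at.
#' @param flatThreshold concavity depth (px) below which a border is flat.
#' @param taperThreshold tapering ratio above which a border is tapered.
#' @param squareBand lengthening-ratio interval read as a square body.
#' @param verticalThreshold lengthening ratio below which a body is
#'   vertical-rectangular.
#' @param deepenedFactor multiple of `flatThreshold` for a deepened concavity.
#' @return Object of class `stageRuleConfig`.
#' @export
stageRules <- function(imageSize = 256, flatThreshold = imageSize / 256,
                       taperThreshold = 1.05, squareBand = c(0.95, 1.05),
                       verticalThreshold = 0.95, deepenedFactor = 2) {
  if (flatThreshold <= 0) stop("flatThreshold must be > 0")
  if (squareBand[1] > squareBand[2]) stop("squareBand bounds must be ordered")
  structure(
    list(
      flatThreshold = flatThreshold, taperThreshold = taperThreshold,
      squareBand = squareBand, verticalThreshold = verticalThreshold,
      deepenedThreshold = deepenedFactor * flatThreshold
    ),
    class = "stageRuleConfig"
  )
}

#' Stage from cephalometric features
#'
#' Deterministic decision cascade over the features of C2, C3 and C4,
#' evaluated from the most mature stage downward with the first match
#' winning (later stages subsume the concavities of earlier ones):
#' all three lower borders concave and at least one of C3/C4
#' vertical-rectangular with deepened C3 and C4 concavities gives CS6;
#' all three concave with at least one square body gives CS5; all three
#' concave gives CS4; concavities on C2 and C3 give CS3; on C2 alone CS2;
#' otherwise CS1. The cascade is total: every finite feature triple maps to
#' exactly one stage.
#'
#' @param c2,c3,c4 feature lists as from [cephFeatures()].
#' @param rules a [stageRules()] configuration.
#' @return Stage label (ordered factor, one of CS1..CS6).
#' @export
stageFromFeatures <- function(c2, c3, c4, rules = stageRules()) {
  conc <- c(c2$concavity, c3$concavity, c4$concavity) > rules$flatThreshold
  inBand <- function(x) x >= rules$squareBand[1] & x <= rules$squareBand[2]
  vertical <- c(c3$lengthening, c4$lengthening) < rules$verticalThreshold
  square <- inBand(c(c3$lengthening, c4$lengthening))
  deepened <- c3$concavity >= rules$deepenedThreshold &&
    c4$concavity >= rules$deepenedThreshold
  s <- if (all(conc) && any(vertical) && deepened) 6L
  else if (all(conc) && any(square)) 5L
  else if (all(conc)) 4L
  else if (conc[1] && conc[2]) 3L
  else if (conc[1]) 2L
  else 1L
  asStage(s)
}

#' Stage directly from three landmark sets
#' @param c2,c3,c4 landmark matrices as from [landmarkSet()].
#' @param rules a [stageRules()] configuration.
#' @return Stage label.
#' @export
stageFromLandmarks <- function(c2, c3, c4, rules = stageRules()) {
  stageFromFeatures(cephFeatures(c2), cephFeatures(c3), cephFeatures(c4),
                    rules)
}

.landmarksFromRow <- function(row, vertebra) {
  pick <- function(p) {
    c(row[[paste(vertebra, p, "x", sep = ".")]],
      row[[paste(vertebra, p, "y", sep = ".")]])
  }
  landmarkSet(pick("Cla"), pick("Clp"), pick("Cm"), pick("Cua"), pick("Cup"))
}

#' Rule-based stages for a whole dataset
#'
#' Applies the decision cascade to the stored ground-truth landmarks of each
#' sample, with thresholds scaled to the dataset's render size.
#'
#' @param ds a [CvmDataset] (or a manifest-like data frame with the landmark
#'   columns).
#' @param rules optional [stageRules()]; defaults to rules scaled to the
#'   dataset's generator image size.
#' @return Ordered factor of predicted stages.
#' @export
stagesFromLandmarks <- function(ds, rules = NULL) {
  if (is(ds, "CvmDataset")) {
    df <- as.data.frame(ds@landmarks)
    if (is.null(rules)) rules <- stageRules(imageSize = ds@config@imageSize)
  } else {
    df <- as.data.frame(ds)
    if (is.null(rules)) rules <- stageRules()
  }
  out <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    out[i] <- stageIndex(stageFromLandmarks(
      .landmarksFromRow(row, "C2"), .landmarksFromRow(row, "C3"),
      .landmarksFromRow(row, "C4"), rules
    ))
  }
  asStage(out)
}
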