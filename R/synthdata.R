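# Synthetic vertebra-image generator. Renders three stacked vertebral bodies
# (the C2 lower border plus stub, and full C3 and C4 bodies) whose lower-border
# concavity, superior-border tapering and body aspect ratio follow the
# six-stage CVM morphology, with ground-truth landmarks.

#' Default per-stage morphology parameter table
#'
#' Ranges are expressed at a 256-px reference scale and scaled linearly with
#' the configured image size. Concavity depths (`conc*`) and inter-body gaps
#' (`gap`) are in pixels; tapering (posterior/anterior height) and lengthening
#' (base/anterior height) ratios are dimensionless. The table encodes the
#' morphological progression: flat lower borders and strong tapering at CS1;
#' a concavity appearing on C2 (CS2), then C3 (CS3), then C4 (CS4);
#' square bodies and reduced inter-body spaces at CS5; deepened concavities
#' and vertical-rectangular bodies at CS6.
#'
#' @return data.frame with six rows (CS1..CS6).
#' @export
defaultStageTable <- function() {
  data.frame(
    stage = stageLevels(),
    conc2_lo = c(0, 6, 6, 6, 7, 14), conc2_hi = c(0, 10, 10, 10, 11, 20),
    conc3_lo = c(0, 0, 6, 6, 7, 14), conc3_hi = c(0, 0, 10, 10, 11, 20),
    conc4_lo = c(0, 0, 0, 6, 7, 14), conc4_hi = c(0, 0, 0, 10, 11, 20),
    taper_lo = c(1.15, 1.15, 1.06, 1.00, 0.98, 0.95),
    taper_hi = c(1.30, 1.30, 1.14, 1.06, 1.04, 1.02),
    len3_lo  = c(1.30, 1.25, 1.15, 1.15, 0.96, 0.75),
    len3_hi  = c(1.55, 1.50, 1.40, 1.40, 1.04, 0.90),
    len4_lo  = c(1.30, 1.25, 1.15, 1.15, 1.06, 0.78),
    len4_hi  = c(1.55, 1.50, 1.40, 1.40, 1.20, 0.92),
    gap_lo   = c(8, 8, 8, 8, 4, 4),
    gap_hi   = c(11, 11, 11, 11, 6, 6),
    row.names = stageLevels()
  )
}

#' Construct a generator configuration
#'
#' @param imageSize raster side in pixels.
#' @param nPerClass number of samples generated per stage.
#' @param noiseSd standard deviation of additive Gaussian noise (intensity
#'   units on the [0, 1] scale).
#' @param rotationJitter maximum absolute rotation in degrees.
#' @param scaleJitter maximum relative scale deviation (fraction).
#' @param backgroundGradient amplitude of the low-frequency background ramp.
#' @param brightnessJitter maximum absolute per-image brightness offset.
#' @param contrastRange range of the per-image multiplicative gain.
#' @param foreground,background,borderValue rendering intensities in [0, 1].
#' @param seed RNG seed used by [generateDataset()].
#' @param onOutOfBounds `"regenerate"` redraws the jitter when a silhouette
#'   would leave the raster; `"fail"` raises an error.
#' @param stageTable per-stage morphology table, see [defaultStageTable()].
#' @return A validated [GeneratorConfig] object.
#' @export
generatorConfig <- function(imageSize = 128, nPerClass = 100, noiseSd = 0.02,
                            rotationJitter = 3, scaleJitter = 0.04,
                            backgroundGradient = 0.10, brightnessJitter = 0.05,
                            contrastRange = c(0.9, 1.0), foreground = 0.75,
                            background = 0.15, borderValue = 0.95, seed = 1,
                            onOutOfBounds = "regenerate",
                            stageTable = defaultStageTable()) {
  new("GeneratorConfig",
    imageSize = imageSize, nPerClass = nPerClass, noiseSd = noiseSd,
    rotationJitter = rotationJitter, scaleJitter = scaleJitter,
    backgroundGradient = backgroundGradient,
    brightnessJitter = brightnessJitter, contrastRange = contrastRange,
    foreground = foreground, background = background,
    borderValue = borderValue, seed = seed, onOutOfBounds = onOutOfBounds,
    stageTable = stageTable
  )
}

#' Generator presets
#'
#' `"easy"`: mild noise and jitter; the benchmark condition for the compact
#' classifier. `"hard"`: dominant per-image brightness/contrast variation
#' with moderate noise and stronger jitter -- a gray-level nuisance regime,
#' calibrated so that the local-entropy transform of these images still
#' shows the vertebral anatomy clearly. `"clean"`: zero noise, zero jitter,
#' no background texture; used for geometric round-trip checks.
#'
#' @param name one of `"easy"`, `"hard"`, `"clean"`.
#' @param ... overrides passed on to [generatorConfig()].
#' @return A [GeneratorConfig].
#' @export
cvmPreset <- function(name = c("easy", "hard", "clean"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    easy = list(),
    hard = list(
      noiseSd = 0.04, rotationJitter = 6, scaleJitter = 0.06,
      backgroundGradient = 0.2, brightnessJitter = 0.3,
      contrastRange = c(0.45, 1.0)
    ),
    clean = list(
      noiseSd = 0, rotationJitter = 0, scaleJitter = 0,
      backgroundGradient = 0, brightnessJitter = 0, contrastRange = c(1, 1)
    )
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(generatorConfig, args)
}

.lmNames <- c("Cla", "Clp", "Cm", "Cua", "Cup")

.makeLandmarks <- function(Cla, Clp, Cm, Cua, Cup) {
  m <- rbind(Cla = Cla, Clp = Clp, Cm = Cm, Cua = Cua, Cup = Cup)
  colnames(m) <- c("x", "y")
  m
}

#' Draw stage-consistent geometry for C2, C3 and C4
#'
#' Samples the morphology parameters for one synthetic subject from the
#' configured per-stage ranges and lays the three bodies out as a vertical
#' stack centered in the raster. At zero jitter the drawn geometry satisfies
#' the generating stage's decision rules exactly (e.g. all concavity depths
#' are 0 for CS1; anterior height exceeds base length on C3/C4 for CS6).
#' Randomness comes from the R session RNG; seed upstream for reproducibility.
#'
#' @param stage stage label (1..6 or "CS1".."CS6").
#' @param config a [GeneratorConfig].
#' @return Named list of three [VertebraGeometry] objects (C2, C3, C4).
#' @export
sampleGeometry <- function(stage, config) {
  s <- stageIndex(stage)
  st <- config@stageTable[s, ]
  u <- config@imageSize / 256
  runit <- function(lo, hi) if (hi > lo) stats::runif(1, lo, hi) else lo

  d2 <- runit(st$conc2_lo, st$conc2_hi) * u
  d3 <- runit(st$conc3_lo, st$conc3_hi) * u
  d4 <- runit(st$conc4_lo, st$conc4_hi) * u
  taper3 <- runit(st$taper_lo, st$taper_hi)
  taper4 <- runit(st$taper_lo, st$taper_hi)
  len3 <- runit(st$len3_lo, st$len3_hi)
  len4 <- runit(st$len4_lo, st$len4_hi)
  g1 <- runit(st$gap_lo, st$gap_hi) * u
  g2 <- runit(st$gap_lo, st$gap_hi) * u
  b2 <- stats::runif(1, 52, 62) * u
  b3 <- stats::runif(1, 52, 62) * u
  b4 <- stats::runif(1, 52, 62) * u
  s2 <- stats::runif(1, 16, 22) * u

  a3 <- b3 / len3; p3 <- taper3 * a3
  a4 <- b4 / len4; p4 <- taper4 * a4
  hmax3 <- max(p3, a3); hmax4 <- max(p4, a4)

  S <- config@imageSize
  total <- s2 + d2 + g1 + hmax3 + d3 + g2 + hmax4 + d4
  y2 <- (S - total) / 2 + s2
  y3 <- y2 + d2 + g1 + hmax3
  y4 <- y3 + d3 + g2 + hmax4
  xc <- S / 2

  c2 <- new("VertebraGeometry",
    landmarks = .makeLandmarks(
      Cla = c(xc + b2 / 2, y2), Clp = c(xc - b2 / 2, y2),
      Cm = c(xc, y2 + d2),
      Cua = c(xc + b2 / 2, y2 - s2), Cup = c(xc - b2 / 2, y2 - s2)
    ),
    concavityDepth = d2, posteriorHeight = s2, anteriorHeight = s2,
    baseLength = b2
  )
  c3 <- new("VertebraGeometry",
    landmarks = .makeLandmarks(
      Cla = c(xc + b3 / 2, y3), Clp = c(xc - b3 / 2, y3),
      Cm = c(xc, y3 + d3),
      Cua = c(xc + b3 / 2, y3 - a3), Cup = c(xc - b3 / 2, y3 - p3)
    ),
    concavityDepth = d3, posteriorHeight = p3, anteriorHeight = a3,
    baseLength = b3
  )
  c4 <- new("VertebraGeometry",
    landmarks = .makeLandmarks(
      Cla = c(xc + b4 / 2, y4), Clp = c(xc - b4 / 2, y4),
      Cm = c(xc, y4 + d4),
      Cua = c(xc + b4 / 2, y4 - a4), Cup = c(xc - b4 / 2, y4 - p4)
    ),
    concavityDepth = d4, posteriorHeight = p4, anteriorHeight = a4,
    baseLength = b4
  )
  list(C2 = c2, C3 = c3, C4 = c4)
}

# Quadratic Bezier through P0 and P2 that passes through M at t = 0.5.
.bezierThrough <- function(P0, M, P2, n = 33) {
  P1 <- 2 * M - (P0 + P2) / 2
  t <- seq(0, 1, length.out = n)
  cbind(
    (1 - t)^2 * P0[1] + 2 * t * (1 - t) * P1[1] + t^2 * P2[1],
    (1 - t)^2 * P0[2] + 2 * t * (1 - t) * P1[2] + t^2 * P2[2]
  )
}

# Closed polygon outline of one vertebra body: upper border, anterior edge,
# curved lower border (through Cm), posterior edge.
.vertebraPolygon <- function(geom) {
  lm <- geom@landmarks
  lower <- .bezierThrough(lm["Cla", ], lm["Cm", ], lm["Clp", ])
  rbind(lm["Cup", ], lm["Cua", ], lower, lm["Clp", ], deparse.level = 0)
}

.affine <- function(pts, theta, scale, center) {
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(scale * (sweep(pts, 2, center) %*% t(R)), 2, center, "+")
}

.transformGeometry <- function(geom, theta, scale, center) {
  lm <- .affine(geom@landmarks, theta, scale, center)
  rownames(lm) <- rownames(geom@landmarks)
  colnames(lm) <- c("x", "y")
  new("VertebraGeometry",
    landmarks = lm,
    concavityDepth = geom@concavityDepth * scale,
    posteriorHeight = geom@posteriorHeight * scale,
    anteriorHeight = geom@anteriorHeight * scale,
    baseLength = geom@baseLength * scale
  )
}

#' Render one synthetic sample
#'
#' Applies the configured rotation/scale jitter to the geometry, rasterizes
#' the three bodies (filled at the foreground intensity with a bright rim)
#' over a textured background, then applies per-image brightness/contrast
#' jitter and additive Gaussian noise. Landmarks are transformed with the
#' same affine map as the silhouettes, so stored coordinates stay consistent
#' with the pixels.
#'
#' @param geometry list of three [VertebraGeometry] as from [sampleGeometry()].
#' @param stage generating stage.
#' @param config a [GeneratorConfig].
#' @return A [SyntheticSample].
#' @export
renderSample <- function(geometry, stage, config) {
  S <- config@imageSize
  center <- c(S / 2, S / 2)
  polys <- lapply(geometry, .vertebraPolygon)

  for (attempt in seq_len(20L)) {
    theta <- if (config@rotationJitter > 0) {
      stats::runif(1, -config@rotationJitter, config@rotationJitter)
    } else 0
    scl <- if (config@scaleJitter > 0) {
      stats::runif(1, 1 - config@scaleJitter, 1 + config@scaleJitter)
    } else 1
    tp <- lapply(polys, .affine, theta = theta, scale = scl, center = center)
    allPts <- do.call(rbind, tp)
    inBounds <- all(allPts >= 1 & allPts <= S - 2)
    if (inBounds) break
    if (config@onOutOfBounds == "fail") {
      stop("geometry out of bounds after jitter")
    }
  }
  if (!inBounds) stop("geometry out of bounds after 20 jitter redraws")

  img <- matrix(config@background, S, S)
  if (config@backgroundGradient > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq_len(S) / S, each = S), S, S)
    gy <- matrix(rep(seq_len(S) / S, times = S), S, S)
    ramp <- (cos(phi) * gx + sin(phi) * gy + 1) / 2
    img <- img + config@backgroundGradient * ramp
  }
  for (pp in tp) {
    mask <- fill_polygon_cpp(S, S, pp[, 1], pp[, 2])
    img[mask] <- config@foreground
  }
  # bright cortical rim: trace the outline densely and mark the pixels
  for (pp in tp) {
    closed <- rbind(pp, pp[1, ])
    seg <- sqrt(rowSums(diff(closed)^2))
    pts <- do.call(rbind, lapply(seq_len(nrow(closed) - 1), function(i) {
      n <- max(2L, ceiling(seg[i] * 2))
      t <- seq(0, 1, length.out = n)
      cbind(
        closed[i, 1] + t * (closed[i + 1, 1] - closed[i, 1]),
        closed[i, 2] + t * (closed[i + 1, 2] - closed[i, 2])
      )
    }))
    rc <- unique(cbind(pmin(pmax(round(pts[, 2]), 0), S - 1) + 1,
                       pmin(pmax(round(pts[, 1]), 0), S - 1) + 1))
    img[rc] <- config@borderValue
  }

  gain <- if (diff(config@contrastRange) > 0) {
    stats::runif(1, config@contrastRange[1], config@contrastRange[2])
  } else config@contrastRange[1]
  offset <- if (config@brightnessJitter > 0) {
    stats::runif(1, -config@brightnessJitter, config@brightnessJitter)
  } else 0
  if (gain != 1 || offset != 0) img <- offset + gain * img
  if (config@noiseSd > 0) {
    img <- img + matrix(stats::rnorm(S * S, 0, config@noiseSd), S, S)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  geomT <- lapply(geometry, .transformGeometry, theta = theta, scale = scl,
                  center = center)
  new("SyntheticSample",
    image = img, stage = stageIndex(stage), geometry = geomT,
    provenance = list(rotation = theta, scale = scl)
  )
}

.landmarkColnames <- function() {
  as.vector(vapply(c("C2", "C3", "C4"), function(v) {
    as.vector(vapply(.lmNames, function(p) {
      paste(v, p, c("x", "y"), sep = ".")
    }, character(2)))
  }, character(10)))
}

.flattenLandmarks <- function(geometry) {
  unlist(lapply(geometry[c("C2", "C3", "C4")], function(g) {
    as.vector(t(g@landmarks[.lmNames, , drop = FALSE]))
  }), use.names = FALSE)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `nPerClass` samples for each of the six stages, assigns disjoint
#' train/validation/test splits class-by-class (balanced by construction),
#' and optionally writes PNG images plus a CSV manifest.
#'
#' @param config a [GeneratorConfig]; its `seed` slot seeds the RNG, so two
#'   calls with the same configuration return identical datasets.
#' @param splitFractions positive fractions summing to 1, named
#'   train/validation/test.
#' @param dir optional output directory; when given, 8-bit grayscale PNGs,
#'   `manifest.csv` and `config.yaml` are written there.
#' @return A [CvmDataset].
#' @export
generateDataset <- function(config,
                            splitFractions = c(train = 0.6, validation = 0.2,
                                               test = 0.2),
                            dir = NULL) {
  stopifnot(length(splitFractions) == 3, all(splitFractions > 0))
  if (abs(sum(splitFractions) - 1) > 1e-8) {
    stop("splitFractions must sum to 1")
  }
  if (is.null(names(splitFractions))) {
    names(splitFractions) <- c("train", "validation", "test")
  }
  set.seed(as.integer(config@seed))
  n <- as.integer(config@nPerClass)
  S <- as.integer(config@imageSize)
  N <- 6L * n
  images <- array(0, dim = c(S, S, N))
  stage <- integer(N)
  lmk <- matrix(NA_real_, N, 30, dimnames = list(NULL, .landmarkColnames()))
  # per-class split counts via cumulative rounding so they sum exactly to n
  cuts <- diff(c(0L, round(cumsum(splitFractions) * n)))
  splitPerClass <- rep(names(splitFractions), times = cuts)

  idx <- 0L
  split <- character(N)
  for (s in 1:6) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      geom <- sampleGeometry(s, config)
      smp <- renderSample(geom, s, config)
      images[, , idx] <- smp@image
      stage[idx] <- s
      lmk[idx, ] <- .flattenLandmarks(smp@geometry)
      split[idx] <- splitPerClass[i]
    }
  }

  path <- rep(NA_character_, N)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
    path <- sprintf("%s_%04d.png", stageLevels()[stage], seq_len(N))
    for (i in seq_len(N)) {
      writeGrayPNG(images[, , i], file.path(dir, path[i]))
    }
  }
  man <- data.frame(
    path = path, split = split, stage = stageLevels()[stage],
    stringsAsFactors = FALSE
  )
  man <- cbind(man, as.data.frame(lmk))
  ds <- new("CvmDataset",
    images = images, stage = asStage(stage),
    split = factor(split, levels = c("train", "validation", "test")),
    landmarks = lmk, manifest = man, config = config
  )
  if (!is.null(dir)) {
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    yaml::write_yaml(generatorConfigAsList(config),
                     file.path(dir, "config.yaml"))
  }
  ds
}

#' Serialize a generator configuration to a plain list
#' @param config a [GeneratorConfig].
#' @return List suitable for `yaml::write_yaml`.
#' @export
generatorConfigAsList <- function(config) {
  list(
    imageSize = config@imageSize, nPerClass = config@nPerClass,
    noiseSd = config@noiseSd, rotationJitter = config@rotationJitter,
    scaleJitter = config@scaleJitter,
    backgroundGradient = config@backgroundGradient,
    brightnessJitter = config@brightnessJitter,
    contrastRange = config@contrastRange, foreground = config@foreground,
    background = config@background, borderValue = config@borderValue,
    seed = config@seed, onOutOfBounds = config@onOutOfBounds,
    stageTable = as.list(config@stageTable[, .stageTableCols])
  )
}

#' Rebuild a generator configuration from a list
#' @param x list as produced by [generatorConfigAsList()] (or parsed YAML).
#' @return A [GeneratorConfig].
#' @export
generatorConfigFromList <- function(x) {
  st <- defaultStageTable()
  if (!is.null(x$stageTable)) {
    for (nm in .stageTableCols) st[[nm]] <- x$stageTable[[nm]]
  }
  x$stageTable <- st
  do.call(generatorConfig, x)
}
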