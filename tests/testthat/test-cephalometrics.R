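lmRect <- function(x0 = 0, y0 = 0, w = 10, h = 10, dip = 0) {
  # axis-aligned body: lower border at y0 (y downward), upper at y0 - h
  landmarkSet(
    Cla = c(x0 + w, y0), Clp = c(x0, y0),
    Cm = c(x0 + w / 2, y0 + dip),
    Cua = c(x0 + w, y0 - h), Cup = c(x0, y0 - h)
  )
}

test_that("concavity depth is the point-to-chord distance, clamped above", {
  lm <- lmRect(0, 0, 10, 10, dip = 2)
  expect_equal(concavityDepth(lm), 2.0)
  expect_equal(concavityDepth(lmRect(dip = 0)), 0.0)
  # Cm above the chord (smaller y) clamps to zero
  expect_equal(concavityDepth(lmRect(dip = -3)), 0.0)
  # slanted chord: Clp=(0,0), Cla=(6,8), Cm=(3,9): |8*3 - 6*9| / 10 = 3
  lm2 <- landmarkSet(Cla = c(6, 8), Clp = c(0, 0), Cm = c(3, 9),
                     Cua = c(6, -2), Cup = c(0, -10))
  expect_equal(concavityDepth(lm2), 3.0)
})

test_that("tapering and lengthening ratios use Euclidean segment lengths", {
  expect_equal(taperingRatio(lmRect(h = 10)), 1.0)
  lmT <- landmarkSet(Cla = c(10, 0), Clp = c(0, 0), Cm = c(5, 0),
                     Cua = c(10, -10), Cup = c(0, -12))
  expect_equal(taperingRatio(lmT), 1.2)

  expect_equal(lengtheningRatio(lmRect(w = 10, h = 10)), 1.0)
  expect_equal(lengtheningRatio(lmRect(w = 15, h = 10)), 1.5)
  expect_equal(lengtheningRatio(lmRect(w = 8, h = 10)), 0.8)

  # rotation invariance: rotate a square body by 45 degrees
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- list(Cla = c(10, 0), Clp = c(0, 0), Cm = c(5, 0),
              Cua = c(10, -10), Cup = c(0, -10))
  rot <- lapply(pts, function(p) as.vector(R %*% p + c(20, 20)))
  lmR <- do.call(landmarkSet, rot)
  expect_equal(taperingRatio(lmR), 1.0, tolerance = 1e-12)
  expect_equal(lengtheningRatio(lmR), 1.0, tolerance = 1e-12)
})

test_that("features are scale-invariant in ratios and linear in depth", {
  set.seed(8)
  for (rep in 1:25) {
    w <- stats::runif(1, 6, 20)
    h <- stats::runif(1, 5, 18)
    dip <- stats::runif(1, 0, 3)
    lm <- lmRect(stats::runif(1, 0, 5), stats::runif(1, 0, 5), w, h, dip)
    s <- stats::runif(1, 0.2, 7)
    f1 <- cephFeatures(lm)
    f2 <- cephFeatures(lm * s)
    expect_equal(f2$concavity, s * f1$concavity, tolerance = 1e-9)
    expect_equal(f2$taper, f1$taper, tolerance = 1e-9)
    expect_equal(f2$lengthening, f1$lengthening, tolerance = 1e-9)
  }
})

feat <- function(conc, len = 1.3, taper = 1.2) {
  list(concavity = conc, taper = taper, lengthening = len)
}

test_that("the decision cascade follows the six-stage morphology", {
  r <- stageRules(imageSize = 256)
  # all flat, tapered -> CS1
  expect_equal(as.character(stageFromFeatures(feat(0), feat(0), feat(0), r)), "CS1")
  # only C2 concave -> CS2
  expect_equal(as.character(stageFromFeatures(feat(5), feat(0), feat(0), r)), "CS2")
  # C2 + C3 -> CS3
  expect_equal(as.character(stageFromFeatures(feat(5), feat(5), feat(0), r)), "CS3")
  # all three, horizontal-rectangular -> CS4
  expect_equal(as.character(
    stageFromFeatures(feat(5), feat(5, 1.3), feat(5, 1.3), r)), "CS4")
  # all three, C3 square -> CS5
  expect_equal(as.character(
    stageFromFeatures(feat(5), feat(5, 1.00), feat(5, 1.3), r)), "CS5")
  # all three deepened, a vertical body -> CS6
  expect_equal(as.character(
    stageFromFeatures(feat(15), feat(15, 0.8), feat(15, 0.85), r)), "CS6")
  # vertical shape but shallow concavities stays CS4 (not deepened)
  expect_equal(as.character(
    stageFromFeatures(feat(1.5), feat(1.5, 0.8), feat(1.5, 0.85), r)), "CS4")
})

test_that("the cascade is total over random finite feature triples", {
  set.seed(14)
  r <- stageRules()
  for (rep in 1:200) {
    fs <- replicate(3, feat(stats::runif(1, 0, 6), stats::runif(1, 0.5, 2),
                            stats::runif(1, 0.8, 1.5)), simplify = FALSE)
    s <- stageFromFeatures(fs[[1]], fs[[2]], fs[[3]], r)
    expect_length(s, 1)
    expect_true(as.character(s) %in% paste0("CS", 1:6))
  }
})

test_that("rule thresholds scale with the render size", {
  r128 <- stageRules(imageSize = 128)
  expect_equal(r128$flatThreshold, 0.5)
  expect_equal(r128$deepenedThreshold, 1.0)
  # a 0.7-px dip is concave at 128-px scale but flat at 256-px scale
  expect_equal(as.character(
    stageFromFeatures(feat(0.7), feat(0), feat(0), r128)), "CS2")
  expect_equal(as.character(
    stageFromFeatures(feat(0.7), feat(0), feat(0), stageRules(256))), "CS1")
})

test_that("landmark invariants are enforced", {
  expect_error(landmarkSet(Cla = c(0, 0), Clp = c(0, 0), Cm = c(0, 0),
                           Cua = c(1, -1), Cup = c(0, -1)), "differ")
  expect_error(landmarkSet(Cla = c(0, 0), Clp = c(10, 0), Cm = c(5, 1),
                           Cua = c(0, -1), Cup = c(10, -1)), "anterior")
  expect_error(landmarkSet(Cla = c(10, 0), Clp = c(0, 0), Cm = c(12, 1),
                           Cua = c(10, -1), Cup = c(0, -1)), "between")
})
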