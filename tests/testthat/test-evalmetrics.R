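test_that("confusion matrix tallies true-by-predicted counts", {
  truth <- rep(1:6, each = 150)
  cm <- confusionMatrix6(truth, truth)
  expect_equal(diag(cm), stats::setNames(rep(150L, 6), paste0("CS", 1:6)))
  expect_equal(sum(cm), 900)

  cm0 <- confusionMatrix6(integer(0), integer(0))
  expect_true(all(cm0 == 0))

  t12 <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6)
  p12 <- c(1, 4, 2, 2, 3, 4, 4, 4, 5, 1, 6, 5)
  cm12 <- confusionMatrix6(t12, p12)
  # hand tally
  expect_equal(cm12["CS1", "CS1"], 1L)
  expect_equal(cm12["CS1", "CS4"], 1L)
  expect_equal(cm12["CS2", "CS2"], 2L)
  expect_equal(cm12["CS4", "CS4"], 2L)
  expect_equal(cm12["CS5", "CS1"], 1L)
  expect_equal(cm12["CS6", "CS5"], 1L)
  expect_equal(sum(cm12), 12)

  expect_error(confusionMatrix6(c(1, 7), c(1, 1)), "1..6")
  expect_error(confusionMatrix6(1:3, 1:2), "equal length")
})

test_that("classification report reproduces the published worked example", {
  cm <- publishedConfusionMatrix()
  rep <- classificationReport(cm)
  pub <- publishedReport()
  expect_equal(rep$perClass$precision_2dp, pub$precision)
  expect_equal(rep$perClass$recall_2dp, pub$recall)
  expect_equal(rep$perClass$f1_2dp, pub$f1)
  expect_equal(rep$perClass$support, pub$support)
  expect_equal(rep$total, 900)
  # spot full-precision values
  expect_equal(rep$perClass$precision[1], 101 / 102)
  expect_equal(rep$perClass$recall[4], 148 / 150)
})

test_that("report handles perfect and degenerate matrices", {
  cm <- diag(150L, 6)
  dimnames(cm) <- list(true = paste0("CS", 1:6), predicted = paste0("CS", 1:6))
  rep <- classificationReport(cm)
  expect_true(all(rep$perClass$precision == 1))
  expect_true(all(rep$perClass$recall == 1))
  expect_true(all(rep$perClass$f1 == 1))
  expect_equal(rep$accuracy, 1)
  expect_false(rep$zeroDivision)

  cm2 <- matrix(0L, 6, 6)
  cm2[1, 1] <- 10L
  rep2 <- classificationReport(cm2)
  expect_true(rep2$zeroDivision)
  expect_equal(rep2$perClass$precision[2], 0)
  expect_equal(rep2$perClass$f1[2], 0)
})

test_that("f1 lies between precision and recall when both are positive", {
  set.seed(9)
  for (rep in 1:30) {
    cm <- matrix(stats::rpois(36, 20), 6, 6)
    r <- classificationReport(cm)
    ok <- r$perClass$precision > 0 & r$perClass$recall > 0
    lo <- pmin(r$perClass$precision, r$perClass$recall)[ok]
    hi <- pmax(r$perClass$precision, r$perClass$recall)[ok]
    expect_true(all(r$perClass$f1[ok] >= lo - 1e-12))
    expect_true(all(r$perClass$f1[ok] <= hi + 1e-12))
    expect_equal(sum(r$perClass$support), sum(cm))
  }
})

test_that("per-class accuracy equals the brute-force one-vs-rest collapse", {
  cm <- publishedConfusionMatrix()
  acc <- perClassAccuracy(cm)
  # independent binary collapse
  brute <- vapply(1:6, function(j) {
    tp <- tn <- 0
    for (a in 1:6) {
      for (b in 1:6) {
        if (a == j && b == j) tp <- tp + cm[a, b]
        if (a != j && b != j) tn <- tn + cm[a, b]
      }
    }
    (tp + tn) / sum(cm)
  }, numeric(1))
  expect_equal(unname(acc), brute)
  expect_equal(unname(acc[1]), (101 + (900 - 150 - 102 + 101)) / 900)

  ident <- diag(10L, 6)
  expect_true(all(perClassAccuracy(ident) == 1))
  onecell <- matrix(0L, 6, 6)
  onecell[1, 1] <- 50L
  expect_true(all(perClassAccuracy(onecell) == 1))
})

test_that("probability grids group samples by true class", {
  n <- 300
  truth <- rep(1:6, each = 50)
  probs <- matrix(1 / 6, n, 6)
  pg <- probabilityGrid(probs, truth)
  expect_length(pg, 6)
  expect_true(all(vapply(pg, dim, integer(2))[1, ] == 6))
  expect_true(all(vapply(pg, dim, integer(2))[2, ] == 50))
  expect_true(all(abs(colSums(pg$CS2) - 1) < 1e-6))
  expect_true(all(pg$CS1 == 1 / 6))

  perfect <- matrix(0, 50, 6)
  perfect[, 3] <- 1
  pg3 <- suppressWarnings(probabilityGrid(perfect, rep(3, 50)))
  expect_true(all(pg3$CS3[3, ] == 1))
  expect_true(all(pg3$CS3[-3, ] == 0))
  ws <- capture_warnings(probabilityGrid(perfect, rep(3, 50)))
  expect_true(any(grepl("CS1", ws)))
  expect_length(ws, 5)  # one warning per absent class
})

test_that("probability grids and confusion matrices write to disk", {
  dir <- file.path(tempdir(), "cvm-eval-test")
  unlink(dir, recursive = TRUE)
  probs <- randomProbMatrix(60, 6)
  pg <- suppressWarnings(probabilityGrid(probs, rep(1:3, each = 20)))
  paths <- writeProbabilityGrid(pg, dir, scale = 2)
  expect_true(all(file.exists(paths)))
  csv <- utils::read.csv(file.path(dir, "probgrid_CS1.csv"))
  expect_equal(dim(csv), c(6, 20))
  p <- writeConfusionCSV(publishedConfusionMatrix(), file.path(dir, "cm.csv"))
  expect_true(file.exists(p))
  unlink(dir, recursive = TRUE)
})

test_that("display rounding is half away from zero at 2 decimals", {
  expect_equal(roundHalfUp(0.675), 0.68)
  expect_equal(roundHalfUp(0.674999), 0.67)
  expect_equal(roundHalfUp(-0.675), -0.68)
  expect_equal(roundHalfUp(0.99499), 0.99)
  expect_equal(roundHalfUp(0.995), 1.00)
})
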