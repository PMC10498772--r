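# Confusion counts, the four metrics and the soft Dice loss.

test_that("confusion counts match hand cases and the brute-force oracle", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  expect_equal(counts(confusionCounts(ones, ones)),
               c(tp = 4, tn = 0, fp = 0, fn = 0))
  expect_equal(counts(confusionCounts(zeros, ones)),
               c(tp = 0, tn = 0, fp = 0, fn = 4))
  set.seed(101)
  for (i in 1:30) {
    p <- randMask(8, 8); t <- randMask(8, 8)
    cc <- counts(confusionCounts(p, t))
    expect_equal(cc, oracleConfusion(p, t))
    expect_equal(sum(cc), 64)
  }
})

test_that("confusion counting validates its inputs", {
  expect_error(confusionCounts(matrix(1, 2, 2), matrix(1, 2, 3)), "mismatch")
  expect_error(confusionCounts(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
  expect_error(ConfusionCounts(-1, 0, 0, 0), "non-negative")
})

test_that("the four metrics evaluate their printed formulas", {
  expect_equal(sensitivity(ConfusionCounts(4, 0, 0, 0)), 1.0)
  expect_equal(sensitivity(ConfusionCounts(0, 0, 4, 0)), 0.0)
  expect_equal(sensitivity(ConfusionCounts(3, 0, 1, 0)), 0.75)
  # the as-printed form uses FP in the denominator; the conventional recall
  # switch uses FN instead
  cc <- ConfusionCounts(tp = 3, tn = 5, fp = 1, fn = 2)
  expect_equal(sensitivity(cc), 3 / 4)
  expect_equal(sensitivity(cc, standard = TRUE), 3 / 5)
  expect_equal(specificity(ConfusionCounts(0, 4, 0, 0)), 1.0)
  expect_equal(specificity(ConfusionCounts(0, 0, 4, 0)), 0.0)
  expect_equal(specificity(ConfusionCounts(0, 9, 1, 0)), 0.9)
  expect_equal(diceCoefficient(ConfusionCounts(4, 0, 0, 0)), 1.0)
  expect_equal(diceCoefficient(ConfusionCounts(0, 0, 2, 2)), 0.0)
  expect_equal(diceCoefficient(ConfusionCounts(3, 0, 1, 2)), 6 / 9)
  expect_equal(iou(ConfusionCounts(4, 0, 0, 0)), 1.0)
  expect_equal(iou(ConfusionCounts(0, 0, 2, 2)), 0.0)
  expect_equal(iou(ConfusionCounts(3, 0, 1, 2)), 0.5)
})

test_that("degenerate denominators follow the configured policy", {
  empty <- ConfusionCounts(0, 4, 0, 0)
  expect_warning(v <- diceCoefficient(empty), "degenerate")
  expect_equal(v, 1.0)
  expect_warning(v <- iou(empty, degenerate = "zero"), "degenerate")
  expect_equal(v, 0.0)
  expect_warning(v <- sensitivity(empty, degenerate = "na"), "degenerate")
  expect_true(is.na(v))
})

test_that("IoU/Dice identity and specificity monotonicity hold on random counts", {
  set.seed(77)
  for (i in 1:50) {
    v <- rmultinom(1, 200, c(0.2, 0.5, 0.15, 0.15))[, 1]
    cc <- ConfusionCounts(v[1] + 1, v[2] + 1, v[3] + 1, v[4] + 1)
    d <- diceCoefficient(cc); j <- iou(cc)
    expect_true(all(c(sensitivity(cc), specificity(cc), d, j) >= 0))
    expect_true(all(c(sensitivity(cc), specificity(cc), d, j) <= 1))
    expect_lte(j, d)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    # flipping one FP pixel to TN never decreases specificity
    if (cc@fp > 0) {
      cc2 <- ConfusionCounts(cc@tp, cc@tn + 1, cc@fp - 1, cc@fn)
      expect_gte(specificity(cc2), specificity(cc))
    }
  }
})

test_that("dice loss reproduces closed forms and the binary-mask identity", {
  y <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(diceLoss(y, y, eps = 0), 0.0, tolerance = 1e-12)
  disjoint <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(diceLoss(disjoint, y, eps = 0), 1.0, tolerance = 1e-12)
  expect_equal(diceLoss(matrix(0.5, 2, 2), y, eps = 0), 1 / 3,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    p <- randMask(6, 6); t <- randMask(6, 6, 0.4)
    if (sum(t) == 0) next
    expect_equal(diceLoss(p, t, eps = 0),
                 1 - diceCoefficient(confusionCounts(p, t)),
                 tolerance = 1e-12)
  }
})

test_that("dice loss is invariant under joint spatial permutation", {
  set.seed(9)
  p <- matrix(runif(36), 6, 6)
  t <- randMask(6, 6)
  perm <- sample(36)
  p2 <- matrix(as.vector(p)[perm], 6, 6)
  t2 <- matrix(as.vector(t)[perm], 6, 6)
  expect_equal(diceLoss(p, t), diceLoss(p2, t2), tolerance = 1e-14)
})

test_that("batch dice loss averages per-image losses, and guards empty masks", {
  y1 <- matrix(c(1, 1, 0, 0), 2, 2); y2 <- matrix(c(1, 0, 0, 0), 2, 2)
  p1 <- matrix(0.5, 2, 2); p2 <- matrix(0.25, 2, 2)
  batchP <- array(c(p1, p2), dim = c(2, 2, 1, 2))
  batchY <- array(c(y1, y2), dim = c(2, 2, 1, 2))
  expect_equal(diceLoss(batchP, batchY, eps = 0),
               mean(c(diceLoss(p1, y1, eps = 0), diceLoss(p2, y2, eps = 0))),
               tolerance = 1e-12)
  z <- matrix(0, 2, 2)
  expect_error(diceLoss(z, z, eps = 0), "empty")
  expect_equal(diceLoss(z, z, eps = 1e-6), 0.0)  # agreement on emptiness
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "mismatch")
  expect_error(diceLoss(matrix(2, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
})

test_that("evaluateSegmentation composes binarization with the metric ops", {
  t <- randMask(16, 16, 0.2)
  ev <- evaluateSegmentation(t, t)
  expect_equal(unlist(ev[c("sensitivity", "specificity", "dice", "iou")]),
               c(sensitivity = 1, specificity = 1, dice = 1, iou = 1))
  inv <- suppressWarnings(evaluateSegmentation(1 - t, t))
  expect_equal(inv$dice, 0.0)
  expect_equal(inv$iou, 0.0)
  set.seed(33)
  pred <- matrix(runif(256), 16, 16)
  truth <- randMask(16, 16)
  ev <- evaluateSegmentation(pred, truth, threshold = 0.5)
  cc <- confusionCounts((pred >= 0.5) * 1, truth)
  expect_equal(counts(ev$counts), counts(cc))
  expect_equal(ev$dice, diceCoefficient(cc))
  expect_equal(ev$sensitivity, sensitivity(cc))
  expect_error(evaluateSegmentation(pred, truth, threshold = 1.5), "threshold")
})

test_that("metric reports serialize as 4-decimal key/value lines", {
  ev <- list(sensitivity = 0.90915, dice = 1 / 3)
  lines <- formatMetricReport(ev)
  expect_equal(lines, c("sensitivity\t0.9092", "dice\t0.3333"))
  path <- tempfile(fileext = ".txt")
  writeMetricReport(ev, path)
  expect_equal(readLines(path), lines)
})
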