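# Training loop contracts: frozen parameters at zero learning rate,
# best-on-validation selection, per-image vs pooled evaluation, checkpoints.

test_that("one epoch at learning rate zero leaves parameters untouched", {
  data <- tinyData()
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 21)
  tc <- TrainConfig(batchSize = 4, epochs = 1, learningRate = 0, seed = 21)
  fit <- trainModel(m, data, tc)
  expect_identical(fit$lastModel@params, m@params)
})

test_that("checkpoint selection is the argmin of a dip-then-rise loss curve", {
  # the selection rule itself, on an injected non-monotone sequence
  fake <- c(0.8, 0.55, 0.41, 0.38, 0.44, 0.52, 0.6)
  expect_equal(bestEpoch(fake), 4)
  expect_equal(bestEpoch(c(3, 1, 1, 2)), 2)   # ties -> earlier epoch
  expect_error(bestEpoch(numeric(0)), "empty")
})

test_that("the trainer returns the minimum-validation-loss snapshot", {
  ns <- asNamespace("pdcnet")
  data <- tinyData(n = 4)
  cfg <- tinyModelConfig()
  tc <- TrainConfig(batchSize = 4, epochs = 4, learningRate = 5e-3, seed = 8)
  ck <- tempfile(fileext = ".ckpt")
  fit <- trainModel(buildModel(cfg, seed = 8), data, tc, checkpointPath = ck)
  expect_equal(fit$bestEpoch, which.min(fit$history$val_loss))
  expect_equal(nrow(fit$history), 4)
  expect_named(fit$history,
               c("epoch", "train_loss", "val_loss", "sens", "spec", "dice", "iou"))
  # the saved snapshot reproduces the minimal validation loss
  vp <- ns$validationPass(fit$model, data$val, 4, 0.5)
  expect_equal(vp$loss, min(fit$history$val_loss), tolerance = 1e-9)
  # the on-disk checkpoint is that same snapshot
  reloaded <- loadCheckpoint(ck)
  expect_equal(reloaded@params, fit$model@params)
  expect_true(file.exists(paste0(ck, ".json")))
})

test_that("training twice with one seed is bit-identical", {
  data <- tinyData(n = 4)
  cfg <- tinyModelConfig()
  tc <- TrainConfig(batchSize = 2, epochs = 2, learningRate = 1e-3, seed = 5,
                    dropoutRate = 0.1)
  f1 <- trainModel(buildModel(cfg, seed = 5), data, tc)
  f2 <- trainModel(buildModel(cfg, seed = 5), data, tc)
  expect_identical(f1$lastModel@params, f2$lastModel@params)
  expect_identical(f1$history, f2$history)
})

test_that("per-image mean and pooled-count metrics differ unless proportions match", {
  # two images with different confusion proportions
  t1 <- matrix(0, 4, 4); t1[1:2, 1:2] <- 1          # 4 lesion pixels
  p1 <- t1                                          # perfect -> dice 1
  t2 <- matrix(0, 4, 4); t2[1, 1] <- 1
  p2 <- matrix(0, 4, 4); p2[4, 4] <- 1              # disjoint -> dice 0
  d1 <- diceCoefficient(confusionCounts(p1, t1))
  d2 <- diceCoefficient(confusionCounts(p2, t2))
  meanDice <- mean(c(d1, d2))
  cc <- counts(confusionCounts(p1, t1)) + counts(confusionCounts(p2, t2))
  pooled <- diceCoefficient(ConfusionCounts(cc["tp"], cc["tn"], cc["fp"], cc["fn"]))
  expect_false(isTRUE(all.equal(meanDice, pooled)))
  # identical proportions -> both aggregations agree
  ccSame <- counts(confusionCounts(p1, t1)) * 2
  pooledSame <- diceCoefficient(
    ConfusionCounts(ccSame["tp"], ccSame["tn"], ccSame["fp"], ccSame["fn"]))
  expect_equal(pooledSame, d1)
})

test_that("evaluateModel reports both aggregations with sane ranges", {
  data <- tinyData(n = 3)
  m <- buildModel(tinyModelConfig(), seed = 30)
  ev <- evaluateModel(m, data$val, batchSize = 2)
  expect_equal(nrow(ev$perImage), 3)
  expect_true(all(ev$mean >= 0 & ev$mean <= 1))
  expect_true(all(ev$pooled >= 0 & ev$pooled <= 1))
  expect_equal(sum(counts(ev$pooledCounts)), 3 * 16 * 16)
  expect_error(evaluateModel(m, list(images = list(), masks = list())), "empty")
})

test_that("checkpoints round-trip through disk with a readable manifest", {
  m <- buildModel(tinyModelConfig(variant = "no_pdcm"), seed = 12)
  path <- tempfile(fileext = ".ckpt")
  saveCheckpoint(m, path)
  r <- loadCheckpoint(path)
  expect_identical(r@params, m@params)
  expect_equal(r@config@variant, "no_pdcm")
  mf <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(mf$nParams, nParams(m))
  expect_error(loadCheckpoint(tempfile()), "not found")
})

test_that("the ablation harness tabulates one row per variant, deterministically", {
  data <- tinyData(n = 4)
  tc <- TrainConfig(batchSize = 4, epochs = 1, learningRate = 1e-3, seed = 2)
  base <- tinyModelConfig()
  variants <- list(list(variant = "no_pdcm", useResidual = TRUE),
                   list(variant = "pdcm_previous", useResidual = TRUE))
  t1 <- runAblation(data, tc, base, variants = variants, seed = 2)
  t2 <- runAblation(data, tc, base, variants = variants, seed = 2)
  expect_equal(nrow(t1), 2)
  expect_identical(t1, t2)
  metricCols <- c("sensitivity", "specificity", "dice", "iou")
  expect_true(all(as.matrix(t1[, metricCols]) >= 0 &
                  as.matrix(t1[, metricCols]) <= 1))
})
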