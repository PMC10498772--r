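# Training loop: Adam on the soft Dice loss, per-epoch validation, and
# best-on-validation-loss checkpointing. The ablation harness retrains the
# architecture variants under identical seed and data.

## ---- Adam ------------------------------------------------------------------

adamInit <- function(params) list(m = treeZero(params), v = treeZero(params), t = 0)

adamStep <- function(params, grads, opt, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1
  opt$m <- treeMap(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- treeMap(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  params <- treeMap(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                    params, opt$m, opt$v)
  list(params = params, opt = opt)
}

#' Index of the checkpoint-selection epoch
#'
#' The saved model is the one whose validation loss is smallest over the
#' whole run -- with a dip-then-rise validation curve this is the dip, not
#' the final epoch. Ties break towards the earlier epoch.
#'
#' @param valLosses numeric vector of per-epoch validation losses.
#' @return The 1-based index of the selected epoch.
#' @examples
#' bestEpoch(c(0.9, 0.4, 0.2, 0.3, 0.5))  # 3
#' @export
bestEpoch <- function(valLosses) {
  if (length(valLosses) == 0) stop("empty validation-loss history")
  which.min(valLosses)
}

## ---- dataset helpers -------------------------------------------------------

checkSplit <- function(split, name) {
  if (is.null(split) || length(split$images) == 0)
    stop("split '", name, "' is empty")
  if (length(split$images) != length(split$masks))
    stop("split '", name, "': images and masks differ in length")
  invisible(split)
}

splitBatch <- function(split, idx) {
  list(x = asImageBatch(split$images[idx]),
       y = asImageBatch(split$masks[idx]))
}

# Mean loss and mean per-image metrics over a split, evaluation mode.
validationPass <- function(model, split, batchSize, threshold, eps = 1e-6) {
  n <- length(split$images)
  lossSum <- 0
  mets <- matrix(0, nrow = n, ncol = 4)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    b <- splitBatch(split, idx)
    prob <- netForward(model, b$x, training = FALSE)$prob
    for (j in seq_along(idx)) {
      p1 <- prob[, , 1, j]; y1 <- b$y[, , 1, j]
      lossSum <- lossSum + diceLossGrad(p1, y1, eps, wantGrad = FALSE)$loss
      ev <- suppressWarnings(
        evaluateSegmentation(p1, y1, threshold = threshold))
      mets[idx[j], ] <- c(ev$sensitivity, ev$specificity, ev$dice, ev$iou)
    }
  }
  list(loss = lossSum / n, metrics = colMeans(mets))
}

## ---- training --------------------------------------------------------------

#' Train a segmentation network
#'
#' Minimises the soft Dice loss with Adam. After every epoch the validation
#' loss and metrics are computed in evaluation mode; the returned model is
#' the snapshot with the smallest validation loss (see [bestEpoch()]), and
#' when `checkpointPath` is given that snapshot is written to disk each time
#' a new minimum is reached.
#'
#' @param model a freshly built [PDCNet-class] (or a previous snapshot to
#'   continue from).
#' @param data list with `train` and `val` splits, each a list of `images`
#'   and `masks` (matrices in `[0, 1]` / binary).
#' @param tc a [TrainConfig-class]; its seed fixes shuffling and DropBlock.
#' @param lossEps Dice-loss smoothing constant.
#' @param checkpointPath optional path for best-so-far checkpoints
#'   (see [saveCheckpoint()]).
#' @param historyPath optional CSV path for the per-epoch history
#'   (columns `epoch, train_loss, val_loss, sens, spec, dice, iou`).
#' @param verbose print a line per epoch.
#' @return List with `model` (best snapshot), `lastModel`, `history`
#'   (data.frame) and `bestEpoch`.
#' @export
trainModel <- function(model, data, tc = TrainConfig(), lossEps = 1e-6,
                       checkpointPath = NULL, historyPath = NULL,
                       verbose = FALSE) {
  stopifnot(is(model, "PDCNet"), is(tc, "TrainConfig"))
  checkSplit(data$train, "train"); checkSplit(data$val, "val")
  nTrain <- length(data$train$images)
  params <- model@params
  state <- model@state
  opt <- adamInit(params)
  history <- data.frame()
  bestLoss <- Inf
  bestParams <- params; bestState <- state; bestIdx <- 0L
  epochsSinceBest <- 0L

  withSeed(tc@seed, {
    for (epoch in seq_len(tc@epochs)) {
      ord <- sample.int(nTrain)
      epochLoss <- 0; nBatches <- 0
      for (start in seq(1, nTrain, by = tc@batchSize)) {
        idx <- ord[start:min(start + tc@batchSize - 1, nTrain)]
        b <- splitBatch(data$train, idx)
        cur <- new("PDCNet", config = model@config, params = params,
                   state = state, seed = model@seed)
        fw <- netForward(cur, b$x, training = TRUE)
        state <- fw$state
        lg <- diceLossGrad(fw$prob, b$y, lossEps)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (batch starting at ", start, "); try a smaller learning rate")
        bw <- netBackward(cur, fw$cache, lg$dpred)
        if (tc@learningRate > 0) {
          upd <- adamStep(params, bw$grads, opt, tc@learningRate,
                          tc@beta1, tc@beta2)
          params <- upd$params; opt <- upd$opt
        }
        epochLoss <- epochLoss + lg$loss; nBatches <- nBatches + 1
      }
      evalModel <- new("PDCNet", config = model@config, params = params,
                       state = state, seed = model@seed)
      vp <- validationPass(evalModel, data$val, tc@batchSize, tc@threshold,
                           lossEps)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epochLoss / nBatches, val_loss = vp$loss,
        sens = vp$metrics[1], spec = vp$metrics[2], dice = vp$metrics[3],
        iou = vp$metrics[4]))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                        epoch, epochLoss / nBatches, vp$loss, vp$metrics[3]))
      if (vp$loss < bestLoss) {
        bestLoss <- vp$loss
        bestParams <- params; bestState <- state; bestIdx <- epoch
        epochsSinceBest <- 0L
        if (!is.null(checkpointPath)) saveCheckpoint(evalModel, checkpointPath)
      } else {
        epochsSinceBest <- epochsSinceBest + 1L
      }
      if (tc@patience > 0 && epochsSinceBest >= tc@patience) break
    }
  })
  if (!is.null(historyPath))
    utils::write.csv(history, historyPath, row.names = FALSE)
  best <- new("PDCNet", config = model@config, params = bestParams,
              state = bestState, seed = model@seed)
  last <- new("PDCNet", config = model@config, params = params,
              state = state, seed = model@seed)
  stopifnot(bestIdx == bestEpoch(history$val_loss))
  list(model = best, lastModel = last, history = history, bestEpoch = bestIdx)
}

## ---- evaluation ------------------------------------------------------------

#' Evaluate a model on a data split
#'
#' Reports both the mean of per-image metrics and the pooled-count variants
#' (confusion counts summed over the split before computing each metric);
#' the two coincide only when every image has identical confusion
#' proportions.
#'
#' @param model a [PDCNet-class].
#' @param split list with `images` and `masks`.
#' @param threshold binarization threshold.
#' @param standard conventional-recall switch for sensitivity.
#' @param batchSize forward-pass batch size.
#' @return List with `perImage` (data.frame), `mean` and `pooled` (named
#'   numeric vectors) and `pooledCounts` (a [ConfusionCounts-class]).
#' @export
evaluateModel <- function(model, split, threshold = 0.5, standard = FALSE,
                          batchSize = 16) {
  checkSplit(split, "evaluation")
  n <- length(split$images)
  per <- data.frame(image = seq_len(n), sensitivity = NA_real_,
                    specificity = NA_real_, dice = NA_real_, iou = NA_real_)
  tot <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    b <- splitBatch(split, idx)
    prob <- netForward(model, b$x, training = FALSE)$prob
    for (j in seq_along(idx)) {
      ev <- suppressWarnings(
        evaluateSegmentation(prob[, , 1, j], b$y[, , 1, j],
                             threshold = threshold, standard = standard))
      per[idx[j], 2:5] <- c(ev$sensitivity, ev$specificity, ev$dice, ev$iou)
      tot <- tot + counts(ev$counts)
    }
  }
  cc <- ConfusionCounts(tot["tp"], tot["tn"], tot["fp"], tot["fn"])
  pooled <- c(sensitivity = sensitivity(cc, standard = standard),
              specificity = specificity(cc),
              dice = diceCoefficient(cc), iou = iou(cc))
  list(perImage = per,
       mean = colMeans(per[, 2:5]),
       pooled = pooled,
       pooledCounts = cc)
}

## ---- ablation harness ------------------------------------------------------

#' Retrain and compare architecture variants
#'
#' Trains each requested variant with the same seed and data and tabulates
#' the four evaluation metrics, mirroring the structure of the reference
#' ablation tables (rows = variants, columns = metrics).
#'
#' @param data list with `train` and `val` splits (and optionally `test`,
#'   used for the reported metrics when present).
#' @param tc a [TrainConfig-class] shared by all variants.
#' @param baseConfig a [ModelConfig-class]; its `variant`/`useResidual` are
#'   overridden per row.
#' @param variants list of `list(variant =, useResidual =)` rows. The
#'   default is the residual-ablation grid: no PDCM and full PDCM, each with
#'   and without residual connections.
#' @param seed model-initialisation seed shared by all variants.
#' @return A data.frame with columns `variant`, `residual`, `sensitivity`,
#'   `specificity`, `dice`, `iou`.
#' @export
runAblation <- function(data, tc, baseConfig,
                        variants = list(
                          list(variant = "no_pdcm", useResidual = FALSE),
                          list(variant = "no_pdcm", useResidual = TRUE),
                          list(variant = "pdcm_previous", useResidual = FALSE),
                          list(variant = "pdcm_previous", useResidual = TRUE)),
                        seed = 1) {
  stopifnot(is(baseConfig, "ModelConfig"))
  evalSplit <- if (!is.null(data$test)) data$test else data$val
  rows <- lapply(variants, function(v) {
    cfg <- ModelConfig(depth = baseConfig@depth,
                       baseChannels = baseConfig@baseChannels,
                       inputChannels = baseConfig@inputChannels,
                       variant = v$variant, useResidual = v$useResidual,
                       dilationRates = baseConfig@dilationRates,
                       kernelSize = baseConfig@kernelSize,
                       camReduction = baseConfig@camReduction,
                       dropblockRate = baseConfig@dropblockRate,
                       dropblockSize = baseConfig@dropblockSize)
    model <- buildModel(cfg, seed = seed)
    fit <- trainModel(model, data, tc)
    ev <- evaluateModel(fit$model, evalSplit, threshold = tc@threshold,
                        batchSize = tc@batchSize)
    data.frame(variant = v$variant, residual = v$useResidual,
               sensitivity = ev$mean["sensitivity"],
               specificity = ev$mean["specificity"],
               dice = ev$mean["dice"], iou = ev$mean["iou"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

## ---- checkpoints -----------------------------------------------------------

configToList <- function(cfg) {
  list(depth = cfg@depth, baseChannels = cfg@baseChannels,
       inputChannels = cfg@inputChannels, variant = cfg@variant,
       useResidual = cfg@useResidual, dilationRates = cfg@dilationRates,
       kernelSize = cfg@kernelSize, camReduction = cfg@camReduction,
       dropblockRate = cfg@dropblockRate, dropblockSize = cfg@dropblockSize)
}

configFromList <- function(l) {
  ModelConfig(depth = l$depth, baseChannels = l$baseChannels,
              inputChannels = l$inputChannels, variant = l$variant,
              useResidual = l$useResidual, dilationRates = l$dilationRates,
              kernelSize = l$kernelSize, camReduction = l$camReduction,
              dropblockRate = l$dropblockRate, dropblockSize = l$dropblockSize)
}

#' Save a model checkpoint
#'
#' Writes the weights container plus a plain-text JSON manifest
#' (`<path>.json`) recording the architecture configuration, so checkpoints
#' are self-describing.
#'
#' @param model a [PDCNet-class].
#' @param path checkpoint file path (e.g. `model.ckpt`).
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "PDCNet"))
  saveRDS(list(config = configToList(model@config), params = model@params,
               state = model@state, seed = model@seed),
          path)
  manifest <- c(configToList(model@config),
                list(nParams = treeCount(model@params), format = "pdcnet-checkpoint-1"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' Load a model checkpoint
#' @param path path given to [saveCheckpoint()].
#' @return A [PDCNet-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  new("PDCNet", config = configFromList(obj$config), params = obj$params,
      state = obj$state, seed = obj$seed)
}
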