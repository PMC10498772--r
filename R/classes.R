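#' Per-pixel confusion counts for binary segmentation
#'
#' Holds the four integers underlying all reported metrics: lesion pixels
#' predicted lesion (TP), background predicted background (TN), background
#' predicted lesion (FP) and lesion predicted background (FN).
#'
#' @slot tp,tn,fp,fn non-negative counts.
#' @seealso [confusionCounts()], [sensitivity()], [diceCoefficient()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (length(v) != 4 || anyNA(v)) return("all four counts must be scalar and non-missing")
    if (any(v < 0)) return("confusion counts must be non-negative")
    if (any(v != round(v))) return("confusion counts must be integers")
    TRUE
  }
)

#' Construct a ConfusionCounts object
#' @param tp,tn,fp,fn the four per-pixel agreement counts.
#' @return A [ConfusionCounts-class] object.
#' @examples
#' ConfusionCounts(tp = 3, tn = 10, fp = 1, fn = 2)
#' @export
ConfusionCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

#' @describeIn ConfusionCounts-class the four counts as a named vector.
#' @param x a `ConfusionCounts` object.
#' @export
counts <- function(x) {
  stopifnot(is(x, "ConfusionCounts"))
  c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn)
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: tp =", object@tp, " tn =", object@tn,
      " fp =", object@fp, " fn =", object@fn,
      " (total ", object@tp + object@tn + object@fp + object@fn, " pixels)\n",
      sep = "")
})

#' Configuration of one PDCM / attention block
#'
#' @slot inChannels,outChannels channel counts in and out of the block.
#' @slot dilationRates dilation rates of the three dilated branches
#'   (default 2, 4, 6; must be strictly increasing and positive).
#' @slot kernelSize kernel size of the dilated branches (default 3).
#' @slot usePreviousBranch whether branch k receives the previous branch
#'   output added to the (1x1-projected) module input.
#' @slot useCam whether the fifth branch applies channel attention.
#' @slot camReduction squeeze ratio of the channel attention bottleneck.
#' @slot dropblockRate,dropblockSize DropBlock drop probability and square
#'   block edge used in the basic convolution blocks.
#' @export
setClass("BlockConfig",
  representation(inChannels = "numeric", outChannels = "numeric",
                 dilationRates = "numeric", kernelSize = "numeric",
                 usePreviousBranch = "logical", useCam = "logical",
                 camReduction = "numeric", dropblockRate = "numeric",
                 dropblockSize = "numeric"),
  validity = function(object) {
    d <- object@dilationRates
    if (any(d <= 0) || any(diff(d) <= 0))
      return("dilation rates must be positive and strictly increasing")
    if (object@inChannels < 1 || object@outChannels < 1)
      return("channel counts must be >= 1")
    if (object@kernelSize %% 2 != 1) return("kernel size must be odd")
    if (object@dropblockRate < 0 || object@dropblockRate >= 1)
      return("dropblockRate must be in [0, 1)")
    TRUE
  }
)

#' Construct a BlockConfig
#' @param inChannels,outChannels channel counts.
#' @param dilationRates dilation rates of the dilated branches.
#' @param kernelSize odd kernel size for the dilated branches.
#' @param usePreviousBranch enable progressive branch fusion.
#' @param useCam enable the channel attention branch.
#' @param camReduction channel attention squeeze ratio.
#' @param dropblockRate,dropblockSize DropBlock parameters.
#' @return A [BlockConfig-class] object.
#' @export
BlockConfig <- function(inChannels, outChannels,
                        dilationRates = c(2, 4, 6), kernelSize = 3,
                        usePreviousBranch = TRUE, useCam = TRUE,
                        camReduction = 8, dropblockRate = 0.1,
                        dropblockSize = 5) {
  new("BlockConfig", inChannels = inChannels, outChannels = outChannels,
      dilationRates = dilationRates, kernelSize = kernelSize,
      usePreviousBranch = usePreviousBranch, useCam = useCam,
      camReduction = camReduction, dropblockRate = dropblockRate,
      dropblockSize = dropblockSize)
}

setMethod("show", "BlockConfig", function(object) {
  cat("BlockConfig: ", object@inChannels, " -> ", object@outChannels,
      " channels; dilations {", paste(object@dilationRates, collapse = ","),
      "}; previous-branch fusion ", object@usePreviousBranch,
      "; channel attention ", object@useCam, "\n", sep = "")
})

#' Architecture configuration of the segmentation network
#'
#' @slot depth number of encoder levels (the reference architecture uses 5).
#' @slot baseChannels width of the first encoder level; doubled at each
#'   deeper level.
#' @slot inputChannels image channels (1 for grayscale).
#' @slot variant one of `"no_pdcm"` (plain second convolution),
#'   `"pdcm_no_previous"` (parallel branches, no progressive fusion) or
#'   `"pdcm_previous"` (full progressive fusion).
#' @slot useResidual wrap each level's [conv -> second stage] in an additive
#'   shortcut (1x1 projection where channel counts differ).
#' @slot dilationRates,kernelSize,camReduction,dropblockRate,dropblockSize
#'   block-level defaults applied at every level.
#' @export
setClass("ModelConfig",
  representation(depth = "numeric", baseChannels = "numeric",
                 inputChannels = "numeric", variant = "character",
                 useResidual = "logical", dilationRates = "numeric",
                 kernelSize = "numeric", camReduction = "numeric",
                 dropblockRate = "numeric", dropblockSize = "numeric"),
  validity = function(object) {
    if (object@depth < 2) return("depth must be >= 2")
    if (!object@variant %in% c("no_pdcm", "pdcm_no_previous", "pdcm_previous"))
      return("variant must be no_pdcm, pdcm_no_previous or pdcm_previous")
    if (object@baseChannels < 1) return("baseChannels must be >= 1")
    TRUE
  }
)

#' Construct a ModelConfig
#' @param depth encoder depth (levels); inputs must be divisible by
#'   `2^(depth - 1)`.
#' @param baseChannels first-level channel width.
#' @param inputChannels image channels.
#' @param variant architecture variant (see [ModelConfig-class]).
#' @param useResidual enable residual wrapping of every level.
#' @param dilationRates,kernelSize,camReduction,dropblockRate,dropblockSize
#'   block defaults.
#' @return A [ModelConfig-class] object.
#' @examples
#' ModelConfig(depth = 3, baseChannels = 8)
#' @export
ModelConfig <- function(depth = 5, baseChannels = 16, inputChannels = 1,
                        variant = c("pdcm_previous", "pdcm_no_previous", "no_pdcm"),
                        useResidual = TRUE, dilationRates = c(2, 4, 6),
                        kernelSize = 3, camReduction = 8,
                        dropblockRate = 0.1, dropblockSize = 5) {
  new("ModelConfig", depth = depth, baseChannels = baseChannels,
      inputChannels = inputChannels, variant = match.arg(variant),
      useResidual = useResidual, dilationRates = dilationRates,
      kernelSize = kernelSize, camReduction = camReduction,
      dropblockRate = dropblockRate, dropblockSize = dropblockSize)
}

setMethod("show", "ModelConfig", function(object) {
  ch <- object@baseChannels * 2^(seq_len(object@depth) - 1)
  cat("ModelConfig: depth ", object@depth, ", channels ",
      paste(ch, collapse = "-"), ", variant ", object@variant,
      ", residual ", object@useResidual, "\n", sep = "")
})

#' Optimization configuration
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' 1e-5 and second-moment decay 0.999, batch size 16, 300 epochs, DropBlock
#' rate 0.1, evaluation threshold 0.5.
#'
#' @slot batchSize,epochs minibatch size and epoch count.
#' @slot learningRate Adam step size.
#' @slot beta1,beta2 Adam moment decays (`beta2` is the protocol's
#'   "momentum 0.999").
#' @slot dropoutRate DropBlock drop probability during training.
#' @slot threshold probability threshold for validation metrics.
#' @slot seed RNG seed fixing initialisation, shuffling and DropBlock.
#' @slot patience early-stopping patience in epochs; 0 disables (default).
#' @export
setClass("TrainConfig",
  representation(batchSize = "numeric", epochs = "numeric",
                 learningRate = "numeric", beta1 = "numeric",
                 beta2 = "numeric", dropoutRate = "numeric",
                 threshold = "numeric", seed = "numeric",
                 patience = "numeric"),
  validity = function(object) {
    if (object@batchSize < 1) return("batchSize must be >= 1")
    if (object@learningRate < 0) return("learningRate must be >= 0")
    if (object@threshold <= 0 || object@threshold >= 1)
      return("threshold must lie in (0, 1)")
    TRUE
  }
)

#' Construct a TrainConfig
#' @param batchSize,epochs,learningRate,beta1,beta2,dropoutRate,threshold,seed,patience
#'   see [TrainConfig-class].
#' @return A [TrainConfig-class] object.
#' @export
TrainConfig <- function(batchSize = 16, epochs = 300, learningRate = 1e-5,
                        beta1 = 0.9, beta2 = 0.999, dropoutRate = 0.1,
                        threshold = 0.5, seed = 1, patience = 0) {
  new("TrainConfig", batchSize = batchSize, epochs = epochs,
      learningRate = learningRate, beta1 = beta1, beta2 = beta2,
      dropoutRate = dropoutRate, threshold = threshold, seed = seed,
      patience = patience)
}

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig: batch ", object@batchSize, ", epochs ", object@epochs,
      ", Adam(lr ", object@learningRate, ", beta1 ", object@beta1,
      ", beta2 ", object@beta2, "), seed ", object@seed, "\n", sep = "")
})

#' Parameters of the synthetic lesion phantom generator
#'
#' The defaults encode the target data regime: a lesion occupying well under
#' 5 percent of the image (0.5-3 percent), with an irregular star-convex
#' outline and a low intensity contrast (0.12) against surrounding tissue
#' under Gaussian noise (sigma 0.05).
#'
#' @slot imageSize square image edge in pixels.
#' @slot lesionFracRange two fractions (lo, hi): admissible lesion area as a
#'   fraction of the image; draws outside are rejection-sampled.
#' @slot contrastDelta intensity offset of the lesion over local tissue.
#' @slot noiseSigma standard deviation of additive Gaussian noise.
#' @slot irregularity amplitude of the radial boundary perturbation.
#' @slot seed base RNG seed; each (seed, index) pair is deterministic.
#' @export
setClass("PhantomParams",
  representation(imageSize = "numeric", lesionFracRange = "numeric",
                 contrastDelta = "numeric", noiseSigma = "numeric",
                 irregularity = "numeric", seed = "numeric"),
  validity = function(object) {
    r <- object@lesionFracRange
    if (length(r) != 2 || r[1] <= 0 || r[2] <= r[1] || r[2] >= 0.25)
      return("lesionFracRange must satisfy 0 < lo < hi < 0.25")
    if (object@imageSize < 16) return("imageSize must be >= 16")
    if (object@contrastDelta < 0 || object@contrastDelta > 1)
      return("contrastDelta must lie in [0, 1]")
    if (object@lesionFracRange[1] * object@imageSize^2 < 4)
      return("lesion area range infeasible for this image size")
    TRUE
  }
)

#' Construct PhantomParams
#' @param imageSize,lesionFracRange,contrastDelta,noiseSigma,irregularity,seed
#'   see [PhantomParams-class].
#' @return A [PhantomParams-class] object.
#' @examples
#' PhantomParams(imageSize = 32, seed = 7)
#' @export
PhantomParams <- function(imageSize = 64, lesionFracRange = c(0.005, 0.03),
                          contrastDelta = 0.12, noiseSigma = 0.05,
                          irregularity = 0.4, seed = 1) {
  new("PhantomParams", imageSize = imageSize, lesionFracRange = lesionFracRange,
      contrastDelta = contrastDelta, noiseSigma = noiseSigma,
      irregularity = irregularity, seed = seed)
}

setMethod("show", "PhantomParams", function(object) {
  cat("PhantomParams: ", object@imageSize, "x", object@imageSize,
      " px, lesion fraction [", object@lesionFracRange[1], ", ",
      object@lesionFracRange[2], "], contrast ", object@contrastDelta,
      ", noise ", object@noiseSigma, ", seed ", object@seed, "\n", sep = "")
})

#' Fitted segmentation network
#'
#' Container for the network parameters, the batch-norm running statistics
#' and the architecture configuration. Create with [buildModel()]; apply
#' with [predictProb()].
#'
#' @slot config the [ModelConfig-class] the network was built from.
#' @slot params nested list of numeric parameter arrays.
#' @slot state nested list of batch-norm running statistics.
#' @slot seed the seed used for initialisation.
#' @export
setClass("PDCNet",
  representation(config = "ModelConfig", params = "list", state = "list",
                 seed = "numeric"))

#' @describeIn PDCNet-class the architecture configuration.
#' @param model a `PDCNet` object.
#' @export
modelConfig <- function(model) {
  stopifnot(is(model, "PDCNet"))
  model@config
}

#' @describeIn PDCNet-class total number of trainable scalar parameters.
#' @export
nParams <- function(model) {
  stopifnot(is(model, "PDCNet"))
  treeCount(model@params)
}

setMethod("show", "PDCNet", function(object) {
  cfg <- object@config
  ch <- cfg@baseChannels * 2^(seq_len(cfg@depth) - 1)
  cat("PDCNet segmentation network\n",
      "  variant:   ", cfg@variant,
      if (cfg@useResidual) " + residual" else " (no residual)", "\n",
      "  encoder:   ", paste(ch, collapse = " -> "), " channels, ",
      cfg@depth - 1, " poolings\n",
      "  params:    ", format(treeCount(object@params), big.mark = ","), "\n",
      "  init seed: ", object@seed, "\n", sep = "")
})
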