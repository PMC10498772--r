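# Architectural building blocks: the basic conv unit (conv -> BN -> ReLU ->
# DropBlock), the parallel dilated convolutional module (PDCM), the channel
# attention branch and the residual wrapper. Each block has an *Init building
# its parameter/state trees and forward/backward pairs threading caches.

## ---- basic convolution unit ------------------------------------------------

basicConvInit <- function(cin, cout, k = 3) {
  list(conv = convInit(k, cin, cout), bn = bnInit(cout))
}

basicConvStateInit <- function(cout) list(bn = bnStateInit(cout))

basicConvForward <- function(x, p, state, training = FALSE,
                             dropRate = 0, dropSize = 5) {
  cv <- convForward(x, p$conv, dilation = 1L)
  bn <- bnForward(cv$y, p$bn, state$bn, training)
  rl <- reluForward(bn$y)
  db <- dropblockForward(rl$y, dropRate, dropSize, training)
  list(y = db$y,
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache, db = db$cache),
       state = list(bn = bn$state))
}

basicConvBackward <- function(p, cache, dy) {
  dy <- dropblockBackward(cache$db, dy)
  dy <- reluBackward(cache$rl, dy)
  bn <- bnBackward(p$bn, cache$bn, dy)
  cv <- convBackward(p$conv, cache$cv, bn$dx)
  list(dx = cv$dx, grads = list(conv = cv$grads, bn = bn$grads))
}

## ---- dilated branch: conv (dilated) -> BN -> ReLU --------------------------

branchInit <- function(cin, cout, k) {
  list(conv = convInit(k, cin, cout), bn = bnInit(cout))
}

branchForward <- function(x, p, state, dilation, training) {
  cv <- convForward(x, p$conv, dilation = dilation)
  bn <- bnForward(cv$y, p$bn, state$bn, training)
  rl <- reluForward(bn$y)
  list(y = rl$y,
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache),
       state = list(bn = bn$state))
}

branchBackward <- function(p, cache, dy) {
  dy <- reluBackward(cache$rl, dy)
  bn <- bnBackward(p$bn, cache$bn, dy)
  cv <- convBackward(p$conv, cache$cv, bn$dx)
  list(dx = cv$dx, grads = list(conv = cv$grads, bn = bn$grads))
}

## ---- channel attention -----------------------------------------------------

#' Initialize channel attention parameters
#'
#' Squeeze-excitation style gating: global average pool, a channel-reducing
#' dense map (ratio `reduction`), ReLU, a channel-restoring map and a
#' sigmoid; the resulting per-channel weights in (0, 1) rescale the input.
#'
#' @param channels number of feature channels.
#' @param reduction squeeze ratio (bottleneck width is
#'   `max(1, channels %/% reduction)`).
#' @return A parameter list for [camForward()].
#' @export
camInitParams <- function(channels, reduction = 8) {
  camInit(channels, reduction)
}

#' Apply channel attention to a feature map
#'
#' @param x feature map: H x W x C array (one sample) or H x W x C x N batch.
#' @param params parameters from [camInitParams()].
#' @return Feature map of identical shape; each channel is scaled by a weight
#'   in (0, 1), so for non-negative input the output never exceeds the input.
#' @export
camForward <- function(x, params) {
  squeeze <- FALSE
  if (length(dim(x)) == 3) { x <- array(x, dim = c(dim(x), 1)); squeeze <- TRUE }
  if (length(dim(x)) != 4) stop("x must be an H x W x C (x N) array")
  if (dim(x)[3] < 1) stop("channel count must be >= 1")
  y <- camForwardInternal(x, params)$y
  if (squeeze) y <- array(y, dim = dim(y)[1:3])
  y
}

## ---- PDCM ------------------------------------------------------------------

#' Initialize the parameters of one PDCM
#'
#' Five parallel branches: a 1x1 convolution mapping the input to
#' `outChannels` (branch 1, whose output also plays the role of the
#' channel-matched module input), three dilated `kernelSize` convolutions at
#' the configured dilation rates, and a channel attention branch. Each
#' convolution is followed by batch normalization and ReLU.
#'
#' @param cfg a [BlockConfig-class].
#' @return List with `params` and `state` trees for [pdcmForward()].
#' @export
pdcmInit <- function(cfg) {
  stopifnot(is(cfg, "BlockConfig"))
  cin <- cfg@inChannels; cout <- cfg@outChannels
  params <- list(b1 = branchInit(cin, cout, 1))
  state <- list(b1 = list(bn = bnStateInit(cout)))
  for (i in seq_along(cfg@dilationRates)) {
    nm <- paste0("b", i + 1)
    params[[nm]] <- branchInit(cout, cout, cfg@kernelSize)
    state[[nm]] <- list(bn = bnStateInit(cout))
  }
  if (cfg@useCam) params$cam <- camInit(cout, cfg@camReduction)
  list(params = params, state = state)
}

# Progressive fusion: F1 = 1x1 branch output (the channel-matched input
# F_in'); branch k >= 2 receives F_{k-1} + F1 when usePreviousBranch, else F1
# alone; the module output is the elementwise sum of all branch outputs.
pdcmForwardInternal <- function(x, p, state, cfg, training = FALSE) {
  b1 <- branchForward(x, p$b1, state$b1, 1L, training)
  f1 <- b1$y
  caches <- list(b1 = b1$cache)
  newState <- list(b1 = b1$state)
  outs <- list(f1)
  prevOut <- f1
  for (i in seq_along(cfg@dilationRates)) {
    nm <- paste0("b", i + 1)
    inp <- if (cfg@usePreviousBranch) prevOut + f1 else f1
    br <- branchForward(inp, p[[nm]], state[[nm]], as.integer(cfg@dilationRates[i]),
                        training)
    caches[[nm]] <- br$cache
    newState[[nm]] <- br$state
    outs[[i + 1]] <- br$y
    prevOut <- br$y
  }
  if (cfg@useCam) {
    camIn <- if (cfg@usePreviousBranch) prevOut + f1 else f1
    cm <- camForwardInternal(camIn, p$cam)
    caches$cam <- cm$cache
    outs[[length(outs) + 1]] <- cm$y
  }
  y <- Reduce(`+`, outs)
  list(y = y, cache = caches, state = newState)
}

pdcmBackwardInternal <- function(p, cache, dy, cfg) {
  grads <- list()
  nb <- length(cfg@dilationRates)
  df1 <- dy                     # direct contribution of F1 to the output sum
  dprev <- vector("list", nb)   # gradient flowing into each dilated branch output
  for (i in seq_len(nb)) dprev[[i]] <- dy
  if (cfg@useCam) {
    cm <- camBackwardInternal(p$cam, cache$cam, dy)
    grads$cam <- cm$grads
    if (cfg@usePreviousBranch) {
      dprev[[nb]] <- dprev[[nb]] + cm$dx
      df1 <- df1 + cm$dx
    } else {
      df1 <- df1 + cm$dx
    }
  }
  for (i in rev(seq_len(nb))) {
    nm <- paste0("b", i + 1)
    br <- branchBackward(p[[nm]], cache[[nm]], dprev[[i]])
    if (cfg@usePreviousBranch) {
      if (i > 1) dprev[[i - 1]] <- dprev[[i - 1]] + br$dx
      df1 <- df1 + br$dx       # branch input includes F1 (twice for branch 2)
      if (i == 1) df1 <- df1 + br$dx
    } else {
      df1 <- df1 + br$dx
    }
    grads[[nm]] <- br$grads
  }
  b1 <- branchBackward(p$b1, cache$b1, df1)
  grads$b1 <- b1$grads
  list(dx = b1$dx, grads = grads[names(p)])  # keep the parameter-tree order
}

#' Run one PDCM forward
#'
#' @param x feature map: H x W x C array or H x W x C x N batch with
#'   `C == cfg@inChannels`.
#' @param block a list from [pdcmInit()].
#' @param cfg the [BlockConfig-class] used at initialisation.
#' @param training use batch statistics in the branch batch norms.
#' @return Feature map with `cfg@outChannels` channels and unchanged spatial
#'   size.
#' @export
pdcmForward <- function(x, block, cfg, training = FALSE) {
  squeeze <- FALSE
  if (length(dim(x)) == 3) { x <- array(x, dim = c(dim(x), 1)); squeeze <- TRUE }
  if (dim(x)[3] != cfg@inChannels)
    stop("channel mismatch: input has ", dim(x)[3], ", config expects ",
         cfg@inChannels)
  y <- pdcmForwardInternal(x, block$params, block$state, cfg, training)$y
  if (squeeze) y <- array(y, dim = dim(y)[1:3])
  y
}

## ---- residual wrapper ------------------------------------------------------

#' Add a residual shortcut to a main-path output
#'
#' Returns `fx + x` when the channel counts of `x` and `fx` agree; when they
#' differ, `x` is first passed through the supplied 1x1 projection
#' convolution (no batch norm on the shortcut).
#'
#' @param x block input (H x W x C (x N) array).
#' @param fx main-path output of identical spatial size.
#' @param proj optional projection parameters (`convInit(1, Cin, Cout)`
#'   shaped list with `W`, `b`); required iff channel counts differ.
#' @return `fx + shortcut(x)`.
#' @export
residualForward <- function(x, fx, proj = NULL) {
  squeeze <- FALSE
  if (length(dim(x)) == 3) {
    x <- array(x, dim = c(dim(x), 1)); fx <- array(fx, dim = c(dim(fx), 1))
    squeeze <- TRUE
  }
  if (!identical(dim(x)[c(1, 2, 4)], dim(fx)[c(1, 2, 4)]))
    stop("spatial/batch mismatch between x and F(x)")
  if (dim(x)[3] != dim(fx)[3]) {
    if (is.null(proj))
      stop("channel counts differ (", dim(x)[3], " vs ", dim(fx)[3],
           "); a 1x1 projection is required")
    x <- convForward(x, proj, dilation = 1L)$y
  }
  y <- fx + x
  if (squeeze) y <- array(y, dim = dim(y)[1:3])
  y
}

## ---- residual level block: basicConv -> second stage, shortcut across ------

# The BlockConfig governing the second stage of a level is fully determined
# by the level width and the ModelConfig.
levelBlockCfg <- function(cout, cfg) {
  BlockConfig(inChannels = cout, outChannels = cout,
              dilationRates = cfg@dilationRates,
              kernelSize = cfg@kernelSize,
              usePreviousBranch = cfg@variant == "pdcm_previous",
              useCam = TRUE,
              camReduction = cfg@camReduction,
              dropblockRate = cfg@dropblockRate,
              dropblockSize = cfg@dropblockSize)
}

levelInit <- function(cin, cout, cfg) {
  blockCfg <- levelBlockCfg(cout, cfg)
  params <- list(conv = basicConvInit(cin, cout))
  state <- list(conv = basicConvStateInit(cout))
  if (cfg@variant == "no_pdcm") {
    params$second <- basicConvInit(cout, cout)
    state$second <- basicConvStateInit(cout)
  } else {
    pd <- pdcmInit(blockCfg)
    params$second <- pd$params
    state$second <- pd$state
  }
  if (cfg@useResidual && cin != cout) params$proj <- convInit(1, cin, cout)
  list(params = params, state = state, blockCfg = blockCfg)
}

levelForward <- function(x, p, state, cfg, blockCfg, training = FALSE) {
  dropRate <- if (training) cfg@dropblockRate else 0
  h1 <- basicConvForward(x, p$conv, state$conv, training,
                         dropRate, cfg@dropblockSize)
  if (cfg@variant == "no_pdcm") {
    h2 <- basicConvForward(h1$y, p$second, state$second, training,
                           dropRate, cfg@dropblockSize)
  } else {
    h2 <- pdcmForwardInternal(h1$y, p$second, state$second, blockCfg, training)
  }
  y <- h2$y
  projCache <- NULL
  if (cfg@useResidual) {
    if (!is.null(p$proj)) {
      pr <- convForward(x, p$proj, dilation = 1L)
      y <- y + pr$y
      projCache <- pr$cache
    } else {
      y <- y + x
    }
  }
  list(y = y,
       cache = list(h1 = h1$cache, h2 = h2$cache, proj = projCache),
       state = list(conv = h1$state, second = h2$state))
}

levelBackward <- function(p, cache, dy, cfg, blockCfg) {
  grads <- list()
  dxTotal <- NULL
  if (cfg@useResidual) {
    if (!is.null(p$proj)) {
      pr <- convBackward(p$proj, cache$proj, dy)
      grads$proj <- pr$grads
      dxTotal <- pr$dx
    } else {
      dxTotal <- dy
    }
  }
  if (cfg@variant == "no_pdcm") {
    h2 <- basicConvBackward(p$second, cache$h2, dy)
  } else {
    h2 <- pdcmBackwardInternal(p$second, cache$h2, dy, blockCfg)
  }
  grads$second <- h2$grads
  h1 <- basicConvBackward(p$conv, cache$h1, h2$dx)
  grads$conv <- h1$grads
  dx <- if (is.null(dxTotal)) h1$dx else h1$dx + dxTotal
  list(dx = dx, grads = grads[names(p)])
}
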