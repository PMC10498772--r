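# Full encoder-decoder assembly. Encoder: per level [basic conv -> second
# stage] with optional residual shortcut, then 2x2 max pooling; channel width
# doubles per level. Decoder: 2x2 transposed convolution doubling the spatial
# size, concatenation with the same-resolution encoder features, then the
# same residual level block. Head: 1x1 convolution + sigmoid.

encoderChannels <- function(cfg) cfg@baseChannels * 2^(seq_len(cfg@depth) - 1)

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Build a segmentation network
#'
#' Initialises all parameters (He-normal convolutions, unit-gamma batch
#' norms) under a fixed seed, so two builds with the same configuration and
#' seed are bit-identical.
#'
#' @param cfg a [ModelConfig-class].
#' @param seed RNG seed for initialisation.
#' @return A [PDCNet-class] model.
#' @examples
#' m <- buildModel(ModelConfig(depth = 3, baseChannels = 4), seed = 1)
#' m
#' @export
buildModel <- function(cfg, seed = 1) {
  stopifnot(is(cfg, "ModelConfig"))
  ch <- encoderChannels(cfg)
  depth <- cfg@depth
  withSeed(seed, {
    enc <- vector("list", depth); encS <- vector("list", depth)
    cin <- cfg@inputChannels
    for (l in seq_len(depth)) {
      lv <- levelInit(cin, ch[l], cfg)
      enc[[l]] <- lv$params; encS[[l]] <- lv$state
      cin <- ch[l]
    }
    dec <- vector("list", depth - 1); decS <- vector("list", depth - 1)
    for (l in seq_len(depth - 1)) {
      lv <- levelInit(2 * ch[l], ch[l], cfg)
      dec[[l]] <- list(up = upconvInit(ch[l + 1], ch[l]), block = lv$params)
      decS[[l]] <- list(block = lv$state)
    }
    head <- convInit(1, ch[1], 1)
    new("PDCNet", config = cfg,
        params = list(enc = enc, dec = dec, head = head),
        state = list(enc = encS, dec = decS),
        seed = as.numeric(seed))
  })
}

checkInputSize <- function(cfg, H, W) {
  f <- 2^(cfg@depth - 1)
  if (H %% f != 0 || W %% f != 0)
    stop("input size ", H, "x", W, " is not divisible by 2^(depth-1) = ", f,
         "; pad the image (see padToMultiple) or reduce depth")
}

# Full forward pass. Returns the probability map plus caches (for backward),
# updated batch-norm state and the bottleneck feature dimensions.
netForward <- function(model, x, training = FALSE) {
  cfg <- model@config; depth <- cfg@depth
  ch <- encoderChannels(cfg)
  d <- dim(x)
  checkInputSize(cfg, d[1], d[2])
  if (d[3] != cfg@inputChannels)
    stop("input has ", d[3], " channels; model expects ", cfg@inputChannels)
  p <- model@params; s <- model@state
  caches <- list(enc = vector("list", depth), pool = vector("list", depth - 1),
                 dec = vector("list", depth - 1))
  newState <- s
  skips <- vector("list", depth - 1)
  h <- x
  for (l in seq_len(depth)) {
    bc <- levelBlockCfg(ch[l], cfg)
    lv <- levelForward(h, p$enc[[l]], s$enc[[l]], cfg, bc, training)
    caches$enc[[l]] <- lv$cache
    newState$enc[[l]] <- lv$state
    if (l < depth) {
      skips[[l]] <- lv$y
      pl <- maxpoolForward(lv$y)
      caches$pool[[l]] <- pl$cache
      h <- pl$y
    } else {
      h <- lv$y
    }
  }
  bottleneckDim <- dim(h)
  for (l in rev(seq_len(depth - 1))) {
    up <- upconvForward(h, p$dec[[l]]$up)
    cat4 <- concatChannels(skips[[l]], up$y)
    bc <- levelBlockCfg(ch[l], cfg)
    lv <- levelForward(cat4, p$dec[[l]]$block, s$dec[[l]]$block, cfg, bc, training)
    caches$dec[[l]] <- list(up = up$cache, block = lv$cache, skipC = ch[l])
    newState$dec[[l]]$block <- lv$state
    h <- lv$y
  }
  hd <- convForward(h, p$head, dilation = 1L)
  sg <- sigmoidForward(hd$y)
  caches$head <- hd$cache
  caches$sig <- sg$cache
  list(prob = sg$y, cache = caches, state = newState,
       bottleneckDim = bottleneckDim)
}

# Backward pass from d(loss)/d(prob); returns gradients mirroring the
# parameter tree plus the gradient at the input image.
netBackward <- function(model, cache, dprob) {
  cfg <- model@config; depth <- cfg@depth
  ch <- encoderChannels(cfg)
  p <- model@params
  dy <- sigmoidBackward(cache$sig, dprob)
  hd <- convBackward(p$head, cache$head, dy)
  gradHead <- hd$grads
  dh <- hd$dx
  gradDec <- vector("list", depth - 1)
  dskips <- vector("list", depth - 1)
  for (l in seq_len(depth - 1)) {
    bc <- levelBlockCfg(ch[l], cfg)
    lv <- levelBackward(p$dec[[l]]$block, cache$dec[[l]]$block, dh, cfg, bc)
    dcat <- lv$dx
    sc <- cache$dec[[l]]$skipC
    dskips[[l]] <- dcat[, , seq_len(sc), , drop = FALSE]
    dup <- dcat[, , sc + seq_len(dim(dcat)[3] - sc), , drop = FALSE]
    upb <- upconvBackward(p$dec[[l]]$up, cache$dec[[l]]$up, dup)
    gradDec[[l]] <- list(up = upb$grads, block = lv$grads)
    dh <- upb$dx
  }
  gradEnc <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    dlevel <- if (l < depth) {
      maxpoolBackward(cache$pool[[l]], dh) + dskips[[l]]
    } else {
      dh
    }
    bc <- levelBlockCfg(ch[l], cfg)
    lv <- levelBackward(p$enc[[l]], cache$enc[[l]], dlevel, cfg, bc)
    gradEnc[[l]] <- lv$grads
    dh <- lv$dx
  }
  list(grads = list(enc = gradEnc, dec = gradDec, head = gradHead),
       dinput = dh)
}

# Coerce user-supplied images to an H x W x C x N array.
asImageBatch <- function(images, inputChannels = 1) {
  if (is.list(images)) {
    arr <- array(0, dim = c(dim(images[[1]])[1], dim(images[[1]])[2],
                            inputChannels, length(images)))
    for (i in seq_along(images)) arr[, , 1, i] <- images[[i]]
    return(arr)
  }
  d <- dim(images)
  if (is.matrix(images)) return(array(images, dim = c(d, 1, 1)))
  if (length(d) == 3) return(array(images, dim = c(d[1], d[2], 1, d[3])))
  if (length(d) == 4) return(images)
  stop("images must be a matrix, a 3-d or 4-d array, or a list of matrices")
}

#' Predict lesion probability maps
#'
#' Runs the network in evaluation mode (batch norm uses running statistics,
#' DropBlock disabled). Input values should already be scaled to `[0, 1]`.
#'
#' @param model a [PDCNet-class] model.
#' @param images a matrix (one image), an H x W x N array, an H x W x 1 x N
#'   array or a list of matrices. Spatial size must be divisible by
#'   `2^(depth - 1)`.
#' @return Probability maps in `[0, 1]`, shaped like the input (matrix in,
#'   matrix out; batch in, H x W x N array out).
#' @export
predictProb <- function(model, images) {
  stopifnot(is(model, "PDCNet"))
  single <- is.matrix(images)
  x <- asImageBatch(images, model@config@inputChannels)
  out <- netForward(model, x, training = FALSE)$prob
  if (single) out[, , 1, 1] else out[, , 1, , drop = TRUE]
}

#' Receptive-field report for the parallel branches
#'
#' Measures the effective receptive-field extent of each branch convolution
#' by impulse-response probing: an all-ones kernel is applied to a centred
#' unit impulse and the nonzero output extent is counted. At level `l` the
#' feature grid sits behind `l - 1` poolings, so one feature-space pixel
#' spans `2^(l-1)` input pixels; the input-space extent is the product.
#'
#' @param cfg a [ModelConfig-class].
#' @param probeSize odd feature-grid size used for probing (must exceed the
#'   largest extent).
#' @return A data.frame with one row per level and branch: `level`, `branch`,
#'   `kernel`, `dilation`, `extent` (feature pixels) and `inputExtent`
#'   (input pixels).
#' @examples
#' receptiveFieldReport(ModelConfig(depth = 3, baseChannels = 4))
#' @export
receptiveFieldReport <- function(cfg, probeSize = 31) {
  stopifnot(is(cfg, "ModelConfig"), probeSize %% 2 == 1)
  probe <- function(k, dil) {
    x <- array(0, dim = c(probeSize, probeSize, 1, 1))
    x[(probeSize + 1) / 2, (probeSize + 1) / 2, 1, 1] <- 1
    w <- array(1, dim = c(k, k, 1, 1))
    y <- conv2dForwardCpp(x, w, 0, as.integer(dil))[, , 1, 1]
    rows <- which(rowSums(abs(y)) > 0)
    cols <- which(colSums(abs(y)) > 0)
    max(diff(range(rows)), diff(range(cols))) + 1
  }
  branches <- if (cfg@variant == "no_pdcm") {
    data.frame(branch = "conv", kernel = 3, dilation = 1)
  } else {
    data.frame(
      branch = c("b1", paste0("b", seq_along(cfg@dilationRates) + 1)),
      kernel = c(1, rep(cfg@kernelSize, length(cfg@dilationRates))),
      dilation = c(1, cfg@dilationRates))
  }
  out <- do.call(rbind, lapply(seq_len(cfg@depth), function(l) {
    b <- branches
    b$level <- l
    b$extent <- mapply(probe, b$kernel, b$dilation)
    b$inputExtent <- b$extent * 2^(l - 1)
    b
  }))
  out[, c("level", "branch", "kernel", "dilation", "extent", "inputExtent")]
}
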