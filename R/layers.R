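# Differentiable layer primitives. Every forward returns list(y, cache) (plus
# updated batch-norm state where relevant); every backward consumes the cache
# and upstream gradient and returns list(dx, grads) with grads mirroring the
# layer's parameter tree. Feature maps are H x W x C x N arrays.

## ---- convolution -----------------------------------------------------------

# He-normal initialisation; fan-in = k * k * Cin. Dilation is architectural,
# not a parameter, so it is passed to forward/backward by the block code.
convInit <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  list(
    W = array(rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout)),
    b = numeric(cout)
  )
}

convForward <- function(x, p, dilation = 1L) {
  y <- conv2dForwardCpp(x, p$W, p$b, as.integer(dilation))
  list(y = y, cache = list(x = x, dilation = dilation))
}

convBackward <- function(p, cache, dy) {
  g <- conv2dBackwardCpp(cache$x, p$W, dy, as.integer(cache$dilation))
  list(dx = g$dx, grads = list(W = g$dW, b = g$db))
}

## ---- batch normalization ---------------------------------------------------

bnInit <- function(c) list(gamma = rep(1, c), beta = numeric(c))

bnStateInit <- function(c) list(mean = numeric(c), var = rep(1, c))

# Channel-wise batch norm. Training mode uses batch statistics (biased
# variance) and updates the running estimates with weight `momentum`;
# evaluation mode uses the running estimates.
bnForward <- function(x, p, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, nrow = HW * 1, ncol = C * N)
  # per-channel stats across HW and N
  chIdx <- rep(seq_len(C), times = N)
  if (training) {
    mu <- vapply(seq_len(C), function(c) mean(xm[, chIdx == c]), numeric(1))
    vr <- vapply(seq_len(C), function(c) {
      xc <- xm[, chIdx == c]; mean((xc - mu[c])^2)
    }, numeric(1))
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var  <- (1 - momentum) * state$var + momentum * vr
  } else {
    mu <- state$mean; vr <- state$var
  }
  invstd <- 1 / sqrt(vr + eps)
  muFull <- rep(mu, times = N)[rep(seq_len(C * N), each = HW)]
  isFull <- rep(invstd, times = N)[rep(seq_len(C * N), each = HW)]
  xhat <- (as.vector(xm) - muFull) * isFull
  gFull <- rep(p$gamma, times = N)[rep(seq_len(C * N), each = HW)]
  bFull <- rep(p$beta, times = N)[rep(seq_len(C * N), each = HW)]
  y <- array(gFull * xhat + bFull, dim = d)
  list(y = y,
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training),
       state = state)
}

bnBackward <- function(p, cache, dy) {
  d <- cache$dims; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- HW * N
  dyv <- as.vector(dy)
  xhat <- cache$xhat
  grp <- rep(rep(seq_len(C), times = N), each = HW)  # channel id per element
  dgamma <- as.vector(rowsum(dyv * xhat, grp, reorder = TRUE))
  dbeta <- as.vector(rowsum(dyv, grp, reorder = TRUE))
  gFull <- p$gamma[grp]
  dxhat <- dyv * gFull
  isFull <- cache$invstd[grp]
  if (cache$training) {
    sum1 <- as.vector(rowsum(dxhat, grp))[grp]
    sum2 <- as.vector(rowsum(dxhat * xhat, grp))[grp]
    dx <- isFull / M * (M * dxhat - sum1 - xhat * sum2)
  } else {
    dx <- dxhat * isFull
  }
  list(dx = array(dx, dim = d), grads = list(gamma = dgamma, beta = dbeta))
}

## ---- pointwise nonlinearities ---------------------------------------------

reluForward <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = list(mask = x > 0))
}

reluBackward <- function(cache, dy) dy * cache$mask

sigmoidForward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = list(y = y))
}

sigmoidBackward <- function(cache, dy) dy * cache$y * (1 - cache$y)

## ---- DropBlock -------------------------------------------------------------

# Structured dropout: contiguous `block` x `block` squares are zeroed around
# Bernoulli-sampled centres, and the surviving activations are rescaled to
# preserve the expected sum. Identity when not training or rate <= 0.
dropblockForward <- function(x, rate, block, training) {
  if (!training || rate <= 0) {
    return(list(y = x, cache = list(mask = NULL)))
  }
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  b <- min(block, H, W)
  vh <- H - b + 1; vw <- W - b + 1
  gamma <- rate * (H * W) / (b * b * vh * vw)
  mask <- array(1, dim = d)
  for (n in seq_len(N)) for (c in seq_len(C)) {
    hits <- which(runif(vh * vw) < gamma)
    for (h in hits) {
      i0 <- (h - 1) %% vh + 1
      j0 <- (h - 1) %/% vh + 1
      mask[i0:(i0 + b - 1), j0:(j0 + b - 1), c, n] <- 0
    }
  }
  keep <- sum(mask)
  scale <- if (keep > 0) length(mask) / keep else 0
  maskScaled <- mask * scale
  list(y = x * maskScaled, cache = list(mask = maskScaled))
}

dropblockBackward <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

## ---- channel attention (squeeze-excitation style) --------------------------

camInit <- function(c, reduction = 8L) {
  cr <- max(1L, c %/% as.integer(reduction))
  list(
    W1 = matrix(rnorm(cr * c, sd = sqrt(2 / c)), nrow = cr, ncol = c),
    b1 = numeric(cr),
    W2 = matrix(rnorm(c * cr, sd = sqrt(2 / cr)), nrow = c, ncol = cr),
    b2 = numeric(c)
  )
}

# Global average pool -> channel-reducing conv -> ReLU -> channel-restoring
# conv -> sigmoid; the resulting per-channel weights rescale the input.
camForwardInternal <- function(x, p) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  s <- matrix(colMeans(matrix(x, nrow = HW, ncol = C * N)), nrow = C, ncol = N)
  z1 <- p$W1 %*% s + p$b1
  a1 <- z1 * (z1 > 0)
  z2 <- p$W2 %*% a1 + p$b2
  wgt <- 1 / (1 + exp(-z2))                       # C x N, each entry in (0,1)
  scaleArr <- array(rep(as.vector(wgt), each = HW), dim = d)
  list(y = x * scaleArr,
       cache = list(x = x, s = s, z1 = z1, a1 = a1, wgt = wgt,
                    scaleArr = scaleArr, HW = HW))
}

camBackwardInternal <- function(p, cache, dy) {
  d <- dim(cache$x); HW <- cache$HW; C <- d[3]; N <- d[4]
  dwgt <- matrix(colSums(matrix(dy * cache$x, nrow = HW, ncol = C * N)),
                 nrow = C, ncol = N)
  dz2 <- dwgt * cache$wgt * (1 - cache$wgt)
  dW2 <- dz2 %*% t(cache$a1)
  db2 <- rowSums(dz2)
  da1 <- t(p$W2) %*% dz2
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- dz1 %*% t(cache$s)
  db1 <- rowSums(dz1)
  ds <- t(p$W1) %*% dz1                            # C x N
  dx <- dy * cache$scaleArr +
    array(rep(as.vector(ds / HW), each = HW), dim = d)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## ---- pooling / transposed convolution --------------------------------------

maxpoolForward <- function(x) {
  r <- maxpool2ForwardCpp(x)
  list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

maxpoolBackward <- function(cache, dy) {
  maxpool2BackwardCpp(dy, cache$idx, cache$H, cache$W)
}

upconvInit <- function(cin, cout) {
  sd <- sqrt(2 / (4 * cin))
  list(W = array(rnorm(4 * cin * cout, sd = sd), dim = c(2, 2, cin, cout)),
       b = numeric(cout))
}

upconvForward <- function(x, p) {
  list(y = upconv2ForwardCpp(x, p$W, p$b), cache = list(x = x))
}

upconvBackward <- function(p, cache, dy) {
  g <- upconv2BackwardCpp(cache$x, p$W, dy)
  list(dx = g$dx, grads = list(W = g$dW, b = g$db))
}
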