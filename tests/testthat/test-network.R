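# Encoder-decoder assembly: shape contracts, parameter accounting,
# determinism and gradient flow.

test_that("forward pass preserves shape and stays in [0,1] across a config sweep", {
  set.seed(55)
  for (depth in 2:3) for (base in c(2, 4)) for (S in c(16, 32)) {
    cfg <- tinyModelConfig(depth = depth, baseChannels = base)
    m <- buildModel(cfg, seed = depth * 10 + base)
    x <- matrix(runif(S * S), S, S)
    pr <- predictProb(m, x)
    expect_equal(dim(pr), c(S, S))
    expect_true(all(pr >= 0 & pr <= 1))
  }
  # all-zero input gives finite output
  m <- buildModel(tinyModelConfig(), seed = 2)
  pr <- predictProb(m, matrix(0, 16, 16))
  expect_true(all(is.finite(pr)))
})

test_that("encoder channel width doubles per level (16 to 256 at depth 5)", {
  cfg <- ModelConfig(depth = 5, baseChannels = 16)
  m <- buildModel(cfg, seed = 1)
  widths <- vapply(m@params$enc,
                   function(l) dim(l$conv$conv$W)[4], numeric(1))
  expect_equal(widths, c(16, 32, 64, 128, 256))
})

test_that("bottleneck spatial size is the input halved once per pooling", {
  ns <- asNamespace("pdcnet")
  cfg <- ModelConfig(depth = 3, baseChannels = 2, camReduction = 2,
                     dropblockRate = 0)
  m <- buildModel(cfg, seed = 8)
  x <- array(runif(40 * 24), dim = c(40, 24, 1, 1))
  fw <- ns$netForward(m, x)
  expect_equal(fw$bottleneckDim[1:2], c(10, 6))      # 2 poolings
  expect_equal(dim(fw$prob), dim(x))
})

test_that("parameter counts match the closed-form oracle for every variant", {
  for (variant in c("no_pdcm", "pdcm_no_previous", "pdcm_previous"))
    for (res in c(FALSE, TRUE)) {
      cfg <- ModelConfig(depth = 3, baseChannels = 4, variant = variant,
                         useResidual = res)
      m <- buildModel(cfg, seed = 3)
      expect_equal(nParams(m), oracleNetP(cfg),
                   info = paste(variant, res))
    }
})

test_that("the ablation lattice orders parameter counts correctly", {
  n <- vapply(c("no_pdcm", "pdcm_no_previous", "pdcm_previous"), function(v)
    nParams(buildModel(ModelConfig(depth = 3, baseChannels = 4, variant = v),
                       seed = 1)), numeric(1))
  expect_lt(n[["no_pdcm"]], n[["pdcm_no_previous"]])
  # previous-branch fusion changes dataflow only, never parameters
  expect_equal(n[["pdcm_no_previous"]], n[["pdcm_previous"]])
  # residual wrapping adds exactly the projection convolutions
  cfgR <- ModelConfig(depth = 3, baseChannels = 4, useResidual = TRUE)
  cfgN <- ModelConfig(depth = 3, baseChannels = 4, useResidual = FALSE)
  delta <- nParams(buildModel(cfgR, 1)) - nParams(buildModel(cfgN, 1))
  ch <- 4 * 2^(0:2)
  projEnc <- sum(1 * c(1, ch[1], ch[2]) * ch + ch)     # 1x1 conv per level
  projDec <- sum(1 * (2 * ch[1:2]) * ch[1:2] + ch[1:2])
  expect_equal(delta, projEnc + projDec)
})

test_that("build + forward is bit-identical under a fixed seed", {
  cfg <- tinyModelConfig(depth = 3, baseChannels = 4)
  m1 <- buildModel(cfg, seed = 77); m2 <- buildModel(cfg, seed = 77)
  expect_identical(m1@params, m2@params)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predictProb(m1, x), predictProb(m2, x))
  m3 <- buildModel(cfg, seed = 78)
  expect_false(identical(m1@params, m3@params))
})

test_that("gradient reaches the first convolution in all four ablation variants", {
  ns <- asNamespace("pdcnet")
  set.seed(6)
  x <- array(runif(16 * 16), dim = c(16, 16, 1, 1))
  y <- array(randMask(16, 16, 0.1), dim = c(16, 16, 1, 1))
  grid <- list(c("no_pdcm", FALSE), c("no_pdcm", TRUE),
               c("pdcm_previous", FALSE), c("pdcm_previous", TRUE))
  for (g in grid) {
    cfg <- tinyModelConfig(variant = g[[1]], useResidual = as.logical(g[[2]]))
    m <- buildModel(cfg, seed = 11)
    fw <- ns$netForward(m, x, training = TRUE)
    lg <- ns$diceLossGrad(fw$prob, y)
    bw <- ns$netBackward(m, fw$cache, lg$dpred)
    gnorm <- sqrt(sum(bw$grads$enc[[1]]$conv$conv$W^2))
    expect_gt(gnorm, 0)
  }
})

test_that("backpropagation matches numeric gradients on a tiny network", {
  ns <- asNamespace("pdcnet")
  set.seed(14)
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 14)
  x <- array(runif(8 * 8), dim = c(8, 8, 1, 1))
  y <- array(randMask(8, 8, 0.2), dim = c(8, 8, 1, 1))
  lossOf <- function(model) {
    fw <- ns$netForward(model, x, training = TRUE)
    ns$diceLossGrad(fw$prob, y, wantGrad = FALSE)$loss
  }
  fw <- ns$netForward(m, x, training = TRUE)
  lg <- ns$diceLossGrad(fw$prob, y)
  bw <- ns$netBackward(m, fw$cache, lg$dpred)
  leaves <- list(
    list(get = function(m) m@params$enc[[1]]$second$b3$conv$W,
         set = function(m, v) { m@params$enc[[1]]$second$b3$conv$W <- v; m },
         grad = bw$grads$enc[[1]]$second$b3$conv$W),
    list(get = function(m) m@params$dec[[1]]$up$W,
         set = function(m, v) { m@params$dec[[1]]$up$W <- v; m },
         grad = bw$grads$dec[[1]]$up$W),
    list(get = function(m) m@params$enc[[2]]$second$cam$W2,
         set = function(m, v) { m@params$enc[[2]]$second$cam$W2 <- v; m },
         grad = bw$grads$enc[[2]]$second$cam$W2))
  for (lf in leaves) {
    W <- lf$get(m)
    idx <- sample(seq_along(W), 4)
    ng <- numGradAt(function(WW) lossOf(lf$set(m, WW)), W, idx)
    expect_equal(ng, as.numeric(lf$grad[idx]), tolerance = 1e-4)
  }
})

test_that("invalid inputs raise configuration errors", {
  m <- buildModel(tinyModelConfig(depth = 3), seed = 1)
  expect_error(predictProb(m, matrix(0, 30, 30)), "divisible")
  expect_error(ModelConfig(depth = 1), "depth")
  expect_error(ModelConfig(variant = "spatial_attention"), "should be one of")
})
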