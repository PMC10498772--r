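# PDCM, channel attention and the residual wrapper.

test_that("channel attention preserves shape and attenuates non-negative input", {
  set.seed(21)
  for (C in c(1, 3, 16)) for (H in c(8, 16)) for (W in c(8, 16)) {
    p <- camInitParams(C, reduction = 8)
    x <- array(abs(rnorm(H * W * C)), dim = c(H, W, C))
    y <- camForward(x, p)
    expect_equal(dim(y), dim(x))
    # channel weights are sigmoids, so each lies in (0,1): |y| <= |x|
    expect_true(all(y <= x + 1e-12))
    expect_true(all(y >= 0))
  }
})

test_that("zero-initialised channel attention halves the input and keeps zeros at zero", {
  p <- camInitParams(4, reduction = 2)
  p$W1[] <- 0; p$W2[] <- 0; p$b1[] <- 0; p$b2[] <- 0
  z <- array(0, dim = c(5, 5, 4))
  expect_equal(camForward(z, p), z)        # weights 0.5 scale zeros
  x <- array(rnorm(5 * 5 * 4), dim = c(5, 5, 4))
  expect_equal(camForward(x, p), x * 0.5, tolerance = 1e-12)
})

test_that("PDCM with all-zero convolutions outputs zero and keeps shapes", {
  cfg <- BlockConfig(inChannels = 3, outChannels = 4, camReduction = 2)
  blk <- pdcmInit(cfg)
  blk$params <- treeMapZero(blk$params)
  x <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  y <- pdcmForward(x, blk, cfg)
  expect_equal(dim(y), c(8, 8, 4))
  expect_equal(max(abs(y)), 0)
  expect_error(pdcmForward(array(0, c(8, 8, 2)), blk, cfg), "channel mismatch")
})

test_that("PDCM output equals the explicit sum of its branch outputs", {
  ns <- asNamespace("pdcnet")
  set.seed(13)
  for (prev in c(FALSE, TRUE)) {
    cfg <- BlockConfig(inChannels = 2, outChannels = 3,
                       usePreviousBranch = prev, camReduction = 2)
    blk <- pdcmInit(cfg)
    x <- array(rnorm(8 * 8 * 2 * 1), dim = c(8, 8, 2, 1))
    y <- ns$pdcmForwardInternal(x, blk$params, blk$state, cfg, FALSE)$y
    # recompute every branch independently and sum
    f1 <- ns$branchForward(x, blk$params$b1, blk$state$b1, 1L, FALSE)$y
    outs <- list(f1); prevOut <- f1
    for (i in 1:3) {
      nm <- paste0("b", i + 1)
      inp <- if (prev) prevOut + f1 else f1
      o <- ns$branchForward(inp, blk$params[[nm]], blk$state[[nm]],
                            as.integer(cfg@dilationRates[i]), FALSE)$y
      outs <- c(outs, list(o)); prevOut <- o
    }
    camIn <- if (prev) prevOut + f1 else f1
    outs <- c(outs, list(ns$camForwardInternal(camIn, blk$params$cam)$y))
    expect_equal(y, Reduce(`+`, outs), tolerance = 1e-12)
  }
})

test_that("branch receptive-field extents follow (k-1)*d+1", {
  rf <- receptiveFieldReport(ModelConfig(depth = 3, baseChannels = 4))
  lvl1 <- rf[rf$level == 1, ]
  expect_equal(lvl1$extent, c(1, 5, 9, 13))
  # extents projected to input space never shrink with depth
  for (b in unique(rf$branch))
    expect_true(all(diff(rf$inputExtent[rf$branch == b]) >= 0))
  rfNo <- receptiveFieldReport(ModelConfig(depth = 2, baseChannels = 4,
                                           variant = "no_pdcm"))
  expect_equal(unique(table(rfNo$level)), 1L)  # single extent per level
})

test_that("residual wrapping returns F(x)+x, with projection when channels differ", {
  x <- array(rnorm(6 * 6 * 3), dim = c(6, 6, 3))
  expect_equal(residualForward(x, x * 0), x)          # zero main path
  expect_equal(residualForward(x, x), 2 * x)          # identity main path
  fx <- array(rnorm(6 * 6 * 5), dim = c(6, 6, 5))
  expect_error(residualForward(x, fx), "projection")
  set.seed(2)
  ns <- asNamespace("pdcnet")
  proj <- ns$convInit(1, 3, 5)
  y <- residualForward(x, fx, proj)
  expect_equal(dim(y), dim(fx))
  expect_equal(y, fx + ns$convForward(array(x, c(6, 6, 3, 1)), proj)$y[, , , 1],
               tolerance = 1e-12)
})

test_that("a zeroed main path passes the upstream gradient through unchanged", {
  ns <- asNamespace("pdcnet")
  cfg <- tinyModelConfig()
  set.seed(4)
  lv <- ns$levelInit(4, 4, cfg)                # matching channels: no projection
  lv$params <- treeMapZero(lv$params)
  x <- array(rnorm(8 * 8 * 4 * 1), dim = c(8, 8, 4, 1))
  fw <- ns$levelForward(x, lv$params, lv$state, cfg, lv$blockCfg, FALSE)
  expect_equal(fw$y, x)                        # identity shortcut
  dy <- array(rnorm(length(x)), dim = dim(x))
  bw <- ns$levelBackward(lv$params, fw$cache, dy, cfg, lv$blockCfg)
  expect_equal(bw$dx, dy, tolerance = 1e-12)   # gradient reproduced exactly
})

test_that("parameter counts order as plain conv < PDCM without CAM < full PDCM", {
  ns <- asNamespace("pdcnet")
  c0 <- 8
  plain <- treeCountLeaves(ns$basicConvInit(c0, c0))
  cfgNoCam <- BlockConfig(inChannels = c0, outChannels = c0, useCam = FALSE)
  cfgCam <- BlockConfig(inChannels = c0, outChannels = c0)
  noCam <- treeCountLeaves(pdcmInit(cfgNoCam)$params)
  full <- treeCountLeaves(pdcmInit(cfgCam)$params)
  expect_lt(plain, noCam)
  expect_lt(noCam, full)
})

test_that("block construction is bit-identical under a fixed seed", {
  cfg <- BlockConfig(inChannels = 3, outChannels = 4)
  make <- function() {
    set.seed(99)
    pdcmInit(cfg)
  }
  a <- make(); b <- make()
  expect_identical(a$params, b$params)
  x <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  expect_identical(pdcmForward(x, a, cfg), pdcmForward(x, b, cfg))
})
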