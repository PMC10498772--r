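# Independent oracles and small fixtures shared across the suite. These are
# deliberately naive implementations (double loops, closed-form counting)
# kept separate from the package's own code paths.

# Brute-force per-pixel confusion counting.
oracleConfusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1
      else if (p == 0 && t == 0) tn <- tn + 1
      else if (p == 1 && t == 0) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

randMask <- function(h, w, p = 0.3) matrix((runif(h * w) < p) * 1, h, w)

# Closed-form parameter counting, independent of the builder.
oracleConvP <- function(k, cin, cout) k * k * cin * cout + cout
oracleBnP <- function(c) 2 * c
oracleBasicP <- function(cin, cout) oracleConvP(3, cin, cout) + oracleBnP(cout)
oracleCamP <- function(c, r) {
  cr <- max(1, c %/% r)
  cr * c + cr + c * cr + c
}
oraclePdcmP <- function(c, r) {
  oracleConvP(1, c, c) + oracleBnP(c) +
    3 * (oracleConvP(3, c, c) + oracleBnP(c)) +
    oracleCamP(c, r)
}
oracleLevelP <- function(cin, c, cfg) {
  second <- if (cfg@variant == "no_pdcm") oracleBasicP(c, c)
            else oraclePdcmP(c, cfg@camReduction)
  proj <- if (cfg@useResidual && cin != c) oracleConvP(1, cin, c) else 0
  oracleBasicP(cin, c) + second + proj
}
oracleNetP <- function(cfg) {
  ch <- cfg@baseChannels * 2^(seq_len(cfg@depth) - 1)
  tot <- 0; cin <- cfg@inputChannels
  for (l in seq_len(cfg@depth)) {
    tot <- tot + oracleLevelP(cin, ch[l], cfg)
    cin <- ch[l]
  }
  for (l in seq_len(cfg@depth - 1)) {
    tot <- tot + (4 * ch[l + 1] * ch[l] + ch[l]) +       # transposed conv
      oracleLevelP(2 * ch[l], ch[l], cfg)
  }
  tot + oracleConvP(1, ch[1], 1)
}

# Shorthands over internal tree utilities.
treeMapZero <- function(t) asNamespace("pdcnet")$treeZero(t)
treeCountLeaves <- function(t) asNamespace("pdcnet")$treeCount(t)

# Central-difference gradient of a scalar function at selected indices.
numGradAt <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

tinyModelConfig <- function(variant = "pdcm_previous", useResidual = TRUE,
                            depth = 2, baseChannels = 2) {
  ModelConfig(depth = depth, baseChannels = baseChannels, variant = variant,
              useResidual = useResidual, camReduction = 2, dropblockRate = 0)
}

tinyPhantomParams <- function(seed = 7, imageSize = 32) {
  PhantomParams(imageSize = imageSize, seed = seed)
}

# Small in-memory dataset for trainer tests. At 16 px the default lesion
# area range falls under the 4-pixel floor, so a wider range is used.
tinyData <- function(n = 4, imageSize = 16, seed = 3) {
  p <- PhantomParams(imageSize = imageSize, seed = seed,
                     lesionFracRange = c(0.02, 0.08))
  ds <- generateDataset(p, n)
  list(train = ds, val = ds)
}
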