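# Seeded lesion-phantom generator. Each phantom is a smooth elliptical
# "head" with low-frequency texture and Gaussian noise, carrying exactly one
# small, irregular, low-contrast lesion whose binary support is the mask.
# Everything is a deterministic function of (seed, index).

phantomStreamSeed <- function(seed, index) {
  (seed * 100003 + index * 7919) %% 2147483646 + 1
}

# Count pixels reachable 4-connectedly from `start` (row, col) inside mask.
floodCount <- function(mask, start) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  queue <- integer(H * W)
  queue[1] <- (start[2] - 1) * H + start[1]
  seen[queue[1]] <- TRUE
  qlen <- 1L; count <- 0L
  while (qlen > 0) {
    cur <- queue[qlen]; qlen <- qlen - 1L
    count <- count + 1L
    i <- (cur - 1L) %% H + 1L
    j <- (cur - 1L) %/% H + 1L
    for (d in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      if (d[1] < 1 || d[1] > H || d[2] < 1 || d[2] > W) next
      lin <- (d[2] - 1L) * H + d[1]
      if (!seen[lin] && mask[lin] == 1) {
        seen[lin] <- TRUE
        qlen <- qlen + 1L
        queue[qlen] <- lin
      }
    }
  }
  count
}

# One rasterised star-convex lesion candidate. Returns mask (0/1 matrix) or
# NULL when the draw misses the admissible area range / connectivity.
drawLesion <- function(S, frac, irregularity, headA, headB, cx0, cy0) {
  r0 <- S * sqrt(frac / pi)
  # random Fourier perturbation of the boundary radius
  kk <- 2:5
  ak <- rnorm(length(kk)) / kk
  bk <- rnorm(length(kk)) / kk
  gFun <- function(theta) {
    g <- rep(0, length(theta))
    for (m in seq_along(kk)) g <- g + ak[m] * cos(kk[m] * theta) +
        bk[m] * sin(kk[m] * theta)
    mx <- max(abs(g), 1e-9)
    g / mx
  }
  rmax <- 1.8 * r0
  # place the centre inside the head ellipse eroded by the max radius
  ea <- headA - rmax; eb <- headB - rmax
  if (ea <= 1 || eb <= 1) return(NULL)
  repeat {
    u <- runif(2, -1, 1)
    if (sum(u^2) <= 1) break
  }
  cx <- cx0 + u[1] * ea
  cy <- cy0 + u[2] * eb
  X <- matrix(seq_len(S), S, S)            # row index
  Y <- matrix(seq_len(S), S, S, byrow = TRUE)
  dx <- X - cx; dy <- Y - cy
  theta <- atan2(dy, dx)
  rad <- r0 * (1 + irregularity * gFun(theta))
  rad <- pmin(pmax(rad, max(0.45 * r0, 1.2)), rmax)
  mask <- (sqrt(dx^2 + dy^2) <= rad) * 1
  if (sum(mask) < 4) return(NULL)
  start <- c(round(cx), round(cy))
  if (start[1] < 1 || start[1] > S || start[2] < 1 || start[2] > S ||
      mask[start[1], start[2]] != 1)
    return(NULL)
  if (floodCount(mask, start) != sum(mask)) return(NULL)
  mask
}

#' Generate one phantom image/mask pair
#'
#' The image is an elliptical head region (low-frequency cosine texture over
#' a uniform tissue intensity) on a dark background; the lesion is a
#' star-convex blob with a randomly Fourier-perturbed boundary radius, its
#' intensity raised by `contrastDelta` over the local tissue; Gaussian noise
#' is added and the result is clamped to `[0, 1]` and quantised to 8 bits so
#' PNG round trips are exact. The lesion area fraction is rejection-sampled
#' into the configured range and the mask is guaranteed 4-connected.
#'
#' @param p a [PhantomParams-class].
#' @param index image index; `(seed, index)` fully determines the output.
#' @return List with `image` (matrix in `[0, 1]`) and `mask` (binary matrix).
#' @examples
#' ph <- generatePhantom(PhantomParams(imageSize = 32, seed = 3), index = 1)
#' mean(ph$mask)  # small foreground fraction
#' @export
generatePhantom <- function(p, index = 1) {
  stopifnot(is(p, "PhantomParams"))
  S <- p@imageSize
  withSeed(phantomStreamSeed(p@seed, index), {
    cx0 <- S / 2 + runif(1, -0.02, 0.02) * S
    cy0 <- S / 2 + runif(1, -0.02, 0.02) * S
    headA <- S * runif(1, 0.36, 0.42)
    headB <- S * runif(1, 0.32, 0.38)
    X <- matrix(seq_len(S), S, S)
    Y <- matrix(seq_len(S), S, S, byrow = TRUE)
    inHead <- ((X - cx0) / headA)^2 + ((Y - cy0) / headB)^2 <= 1
    # low-frequency texture: a few random cosine waves
    tex <- matrix(0, S, S)
    for (k in 1:4) {
      f <- runif(2, 1, 4) / S
      ph <- runif(1, 0, 2 * pi)
      tex <- tex + runif(1, 0.02, 0.05) * cos(2 * pi * (f[1] * X + f[2] * Y) + ph)
    }
    img <- 0.08 + inHead * (0.37 + tex)
    mask <- NULL
    for (attempt in 1:200) {
      frac <- runif(1, p@lesionFracRange[1], p@lesionFracRange[2])
      cand <- drawLesion(S, frac, p@irregularity, headA, headB, cx0, cy0)
      if (is.null(cand)) next
      obs <- sum(cand) / S^2
      if (obs >= p@lesionFracRange[1] && obs <= p@lesionFracRange[2]) {
        mask <- cand; break
      }
    }
    if (is.null(mask))
      stop("could not draw a lesion in the admissible area range; ",
           "the range is infeasible for imageSize ", S)
    img <- img + p@contrastDelta * mask
    img <- img + rnorm(S * S, sd = p@noiseSigma)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 255) / 255          # 8-bit quantisation, PNG-exact
    list(image = img, mask = mask)
  })
}

# Disjoint (seed, index) streams per split.
splitIndexOffset <- c(train = 0, val = 1000000, test = 2000000)

#' Generate an in-memory phantom dataset
#'
#' @param p a [PhantomParams-class].
#' @param n number of image/mask pairs.
#' @param split which index stream to draw from (`"train"`, `"val"`,
#'   `"test"`); streams are disjoint, so the splits never share a phantom.
#' @return List with `images` and `masks` (lists of matrices).
#' @export
generateDataset <- function(p, n, split = "train") {
  off <- splitIndexOffset[[split]]
  pairs <- lapply(seq_len(n), function(i) generatePhantom(p, off + i))
  list(images = lapply(pairs, `[[`, "image"),
       masks = lapply(pairs, `[[`, "mask"))
}

#' Write a train/val/test phantom split to disk
#'
#' Layout: `<root>/{train,val,test}/{images,masks}/NNNN.png` plus a
#' `manifest.json` recording the generator parameters and every file name.
#' Images are 8-bit grayscale PNG; masks are 0/255 PNG. Re-running with the
#' same parameters reproduces byte-identical files.
#'
#' @param p a [PhantomParams-class].
#' @param nTrain,nVal,nTest split sizes (the reference regime uses the ratio
#'   3:1:1).
#' @param dir output root directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest list, invisibly.
#' @export
generateSplit <- function(p, nTrain, nVal, nTest, dir, overwrite = FALSE) {
  stopifnot(is(p, "PhantomParams"), nTrain >= 1, nVal >= 1, nTest >= 1)
  if (dir.exists(dir) && length(list.files(dir, recursive = TRUE)) > 0 &&
      !overwrite)
    stop("output directory ", dir, " is not empty; use overwrite = TRUE")
  sizes <- c(train = nTrain, val = nVal, test = nTest)
  manifest <- list(
    params = list(imageSize = p@imageSize,
                  lesionFracRange = p@lesionFracRange,
                  contrastDelta = p@contrastDelta, noiseSigma = p@noiseSigma,
                  irregularity = p@irregularity, seed = p@seed),
    splits = list())
  for (sp in names(sizes)) {
    imgDir <- file.path(dir, sp, "images")
    mskDir <- file.path(dir, sp, "masks")
    dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(mskDir, recursive = TRUE, showWarnings = FALSE)
    files <- character(sizes[[sp]])
    for (i in seq_len(sizes[[sp]])) {
      pair <- generatePhantom(p, splitIndexOffset[[sp]] + i)
      nm <- sprintf("%s_%04d.png", sp, i)
      png::writePNG(pair$image, file.path(imgDir, nm))
      png::writePNG(pair$mask, file.path(mskDir, nm))
      files[i] <- nm
    }
    manifest$splits[[sp]] <- list(n = sizes[[sp]], files = files,
                                  indexOffset = splitIndexOffset[[sp]])
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}
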