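# Image input/output: PNG pairs, split loading, padded prediction export and
# figure-panel montages. PNG is the canonical raster format (lossless; masks
# must never pass through a lossy codec). A read-only NIfTI slice import is
# offered for real MRI slices.

# Collapse an RGB(A) PNG array to one grayscale channel (mean of RGB).
toGray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  d <- dim(arr)
  if (length(d) == 3) {
    nc <- min(d[3], 3)
    out <- matrix(0, d[1], d[2])
    for (k in seq_len(nc)) out <- out + arr[, , k]
    return(out / nc)
  }
  stop("unsupported PNG layout: ", paste(d, collapse = "x"))
}

#' Load an image (and optionally its mask) from PNG
#'
#' The image is converted to a single grayscale channel in `[0, 1]`. The
#' mask is binarized at the midpoint; if it was not two-valued a validation
#' warning is emitted first.
#'
#' @param imagePath PNG image path.
#' @param maskPath optional PNG mask path (foreground = lesion).
#' @return List with `image` (matrix) and `mask` (binary matrix or `NULL`).
#' @export
loadPair <- function(imagePath, maskPath = NULL) {
  if (!file.exists(imagePath)) stop("image not found: ", imagePath)
  image <- toGray(png::readPNG(imagePath))
  mask <- NULL
  if (!is.null(maskPath)) {
    if (!file.exists(maskPath)) stop("mask not found: ", maskPath)
    mask <- toGray(png::readPNG(maskPath))
    vals <- sort(unique(as.vector(mask)))
    if (length(vals) > 2)
      warning("mask ", maskPath, " is not two-valued (", length(vals),
              " levels); binarizing at 0.5", call. = FALSE)
    mask <- (mask >= 0.5) * 1
    if (!identical(dim(image), dim(mask)))
      stop("image and mask dimensions differ: ",
           paste(dim(image), collapse = "x"), " vs ",
           paste(dim(mask), collapse = "x"))
  }
  list(image = image, mask = mask)
}

#' Load a phantom split written by [generateSplit()]
#'
#' @param dir the split root directory (containing `manifest.json`).
#' @param split `"train"`, `"val"` or `"test"`.
#' @return List with `images` and `masks` (lists of matrices).
#' @export
loadSplit <- function(dir, split = "train") {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  files <- manifest$splits[[split]]$files
  if (is.null(files)) stop("split '", split, "' not present in manifest")
  images <- list(); masks <- list()
  for (i in seq_along(files)) {
    pr <- loadPair(file.path(dir, split, "images", files[i]),
                   file.path(dir, split, "masks", files[i]))
    images[[i]] <- pr$image
    masks[[i]] <- pr$mask
  }
  list(images = images, masks = masks)
}

#' Pad an image so both sides are divisible by a factor
#'
#' Pads on the bottom/right only, so cropping back to the original size is
#' exact. `"reflect"` mirrors the border rows/columns; `"zero"` pads with
#' zeros.
#'
#' @param img matrix.
#' @param factor required divisor (the network needs `2^(depth - 1)`).
#' @param mode `"reflect"` (default) or `"zero"`.
#' @return List with `img` (padded matrix) and `orig` (original `c(H, W)`).
#' @export
padToMultiple <- function(img, factor, mode = c("reflect", "zero")) {
  mode <- match.arg(mode)
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / factor) * factor
  Wp <- ceiling(W / factor) * factor
  if (Hp == H && Wp == W) return(list(img = img, orig = c(H, W)))
  out <- matrix(0, Hp, Wp)
  out[1:H, 1:W] <- img
  if (mode == "reflect") {
    if (Hp > H) out[(H + 1):Hp, 1:W] <- img[H - seq_len(Hp - H) + 1, , drop = FALSE]
    if (Wp > W) out[, (W + 1):Wp] <- out[, W - seq_len(Wp - W) + 1, drop = FALSE]
  }
  list(img = out, orig = c(H, W))
}

#' Segment an image file and write the binary mask
#'
#' Loads the image, pads it to the next multiple of `2^(depth - 1)` (reflect
#' or zero padding), runs the network in evaluation mode, crops back to the
#' original resolution, binarizes at `threshold` and writes a 0/255 PNG.
#'
#' @param model a [PDCNet-class] or the path of a checkpoint saved with
#'   [saveCheckpoint()].
#' @param imagePath input PNG.
#' @param outPath output PNG mask path.
#' @param threshold binarization threshold.
#' @param probPath optional path for the probability map PNG (8-bit).
#' @param padMode `"reflect"` or `"zero"`.
#' @return Invisibly, the binary mask matrix.
#' @export
predictToFile <- function(model, imagePath, outPath, threshold = 0.5,
                          probPath = NULL, padMode = "reflect") {
  if (is.character(model)) model <- loadCheckpoint(model)
  stopifnot(is(model, "PDCNet"))
  img <- loadPair(imagePath)$image
  f <- 2^(model@config@depth - 1)
  pd <- padToMultiple(img, f, mode = padMode)
  prob <- predictProb(model, pd$img)
  prob <- prob[seq_len(pd$orig[1]), seq_len(pd$orig[2]), drop = FALSE]
  mask <- (prob >= threshold) * 1
  png::writePNG(mask, outPath)
  if (!is.null(probPath)) png::writePNG(prob, probPath)
  invisible(mask)
}

#' Render an original / label / prediction montage
#'
#' Lays out one row per case: the original image, the ground-truth mask, and
#' one column per prediction variant, separated by white gutters -- the
#' layout used for qualitative side-by-side comparison of ablation variants.
#' The montage is written as a lossless grayscale PNG, with the column
#' labels in a plain-text sidecar (`<outPath>.labels.txt`).
#'
#' @param images list of image matrices (all the same size).
#' @param truths list of binary ground-truth masks.
#' @param predictions named list of variants, each a list of predicted masks
#'   (one per row). Column count is therefore `2 + length(predictions)`.
#' @param outPath output PNG path.
#' @param gutter gutter width in pixels.
#' @return Invisibly, the montage matrix.
#' @export
renderPanel <- function(images, truths, predictions, outPath, gutter = 2) {
  nr <- length(images)
  if (nr == 0) stop("no rows to render")
  if (length(truths) != nr) stop("images and truths differ in length")
  if (!is.list(predictions) || length(predictions) == 0)
    stop("predictions must be a non-empty named list of variants")
  for (v in predictions)
    if (length(v) != nr) stop("every variant needs one prediction per row")
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  cols <- c(list(original = images, label = truths), predictions)
  nc <- length(cols)
  big <- matrix(1, nr * H + (nr - 1) * gutter, nc * W + (nc - 1) * gutter)
  for (r in seq_len(nr)) for (cix in seq_len(nc)) {
    tile <- cols[[cix]][[r]]
    if (!identical(dim(tile), c(H, W)))
      stop("all tiles must share the same size")
    r0 <- (r - 1) * (H + gutter)
    c0 <- (cix - 1) * (W + gutter)
    big[r0 + seq_len(H), c0 + seq_len(W)] <- tile
  }
  png::writePNG(big, outPath)
  writeLines(names(cols), paste0(outPath, ".labels.txt"))
  invisible(big)
}

#' Read one slice of a NIfTI volume as a normalized grayscale matrix
#'
#' Read-only convenience for real MRI data: the requested axial slice is
#' extracted and min-max scaled to `[0, 1]`. Requires the RNifti package.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param slice slice index along the third axis (default: middle slice).
#' @return A matrix in `[0, 1]`.
#' @export
loadNiftiSlice <- function(path, slice = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI import")
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  m <- if (length(d) == 2) vol[, ] else {
    if (is.null(slice)) slice <- ceiling(d[3] / 2)
    if (slice < 1 || slice > d[3]) stop("slice out of range")
    vol[, , slice]
  }
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}
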