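# Confusion-count metrics and the soft Dice loss.
#
# The four metrics are implemented exactly as the reference definitions
# print them. Note that the printed sensitivity is TP/(TP+FP) -- what most
# of the literature calls precision/PPV. That form is the default so that
# numbers are comparable with the source tables; `standard = TRUE` switches
# sensitivity to the conventional recall TP/(TP+FN). See the methods
# vignette for discussion.

checkBinaryMask <- function(m, what = "mask") {
  if (!is.matrix(m) && !(is.array(m) && length(dim(m)) == 2))
    stop(what, " must be a 2-d matrix")
  if (anyNA(m)) stop(what, " contains missing values")
  if (!all(m == 0 | m == 1))
    stop(what, " must be strictly binary (0/1)")
  invisible(m)
}

checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("dimension mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  invisible(NULL)
}

#' Per-pixel confusion counts between a predicted and a true mask
#'
#' @param pred,truth binary matrices of identical size (1 = lesion).
#' @return A [ConfusionCounts-class] with `tp + tn + fp + fn == prod(dim)`.
#' @examples
#' p <- matrix(c(1, 1, 0, 0), 2, 2)
#' t <- matrix(c(1, 0, 1, 0), 2, 2)
#' confusionCounts(p, t)
#' @export
confusionCounts <- function(pred, truth) {
  checkBinaryMask(pred, "pred"); checkBinaryMask(truth, "truth")
  checkSameShape(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  ConfusionCounts(tp = tp, tn = tn, fp = fp, fn = fn)
}

degenerateValue <- function(policy, what) {
  v <- switch(policy, one = 1.0, zero = 0.0, na = NA_real_)
  warning(what, ": denominator is zero (degenerate case); returning ",
          format(v), call. = FALSE)
  v
}

#' Sensitivity as printed in the reference definition
#'
#' Computes `TP / (TP + FP)` by default -- the form the reference tables use
#' (conventionally called precision). With `standard = TRUE` computes the
#' conventional sensitivity/recall `TP / (TP + FN)`.
#'
#' @param c a [ConfusionCounts-class].
#' @param standard use the conventional recall definition.
#' @param degenerate value policy when the denominator is zero: `"one"`
#'   (default, with a warning), `"zero"` or `"na"`.
#' @return A fraction in `[0, 1]` (or `NA` under the `"na"` policy).
#' @export
sensitivity <- function(c, standard = FALSE,
                        degenerate = c("one", "zero", "na")) {
  degenerate <- match.arg(degenerate)
  den <- if (standard) c@tp + c@fn else c@tp + c@fp
  if (den == 0) return(degenerateValue(degenerate, "sensitivity"))
  c@tp / den
}

#' Specificity `TN / (FP + TN)`
#' @inheritParams sensitivity
#' @return A fraction in `[0, 1]`.
#' @export
specificity <- function(c, degenerate = c("one", "zero", "na")) {
  degenerate <- match.arg(degenerate)
  den <- c@fp + c@tn
  if (den == 0) return(degenerateValue(degenerate, "specificity"))
  c@tn / den
}

#' Dice coefficient `2TP / (2TP + FN + FP)`
#' @inheritParams sensitivity
#' @return A fraction in `[0, 1]`; 1 when prediction and truth are both empty
#'   (perfect agreement on emptiness, with a warning).
#' @export
diceCoefficient <- function(c, degenerate = c("one", "zero", "na")) {
  degenerate <- match.arg(degenerate)
  den <- 2 * c@tp + c@fn + c@fp
  if (den == 0) return(degenerateValue(degenerate, "diceCoefficient"))
  2 * c@tp / den
}

#' Intersection over union `TP / (TP + FN + FP)`
#'
#' Satisfies `iou == dice / (2 - dice)` exactly.
#' @inheritParams sensitivity
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(c, degenerate = c("one", "zero", "na")) {
  degenerate <- match.arg(degenerate)
  den <- c@tp + c@fn + c@fp
  if (den == 0) return(degenerateValue(degenerate, "iou"))
  c@tp / den
}

#' Soft Dice loss
#'
#' `1 - (2 sum(y * p) + eps) / (sum(y^2) + sum(p^2) + eps)` over the pixels of
#' each image; for a batch (H x W x 1 x N array) the per-image losses are
#' averaged, so large lesions do not dominate. The smoothing constant `eps`
#' guards lesion-free images; set `eps = 0` for the exact formula.
#'
#' @param pred probability map: matrix in `[0, 1]`, or an H x W x 1 x N array.
#' @param truth binary mask of matching size.
#' @param eps smoothing constant (default `1e-6`).
#' @return The scalar loss.
#' @examples
#' y <- matrix(c(1, 1, 0, 0), 2, 2)
#' diceLoss(matrix(0.5, 2, 2), y, eps = 0)  # 1/3
#' @export
diceLoss <- function(pred, truth, eps = 1e-6) {
  diceLossGrad(pred, truth, eps, wantGrad = FALSE)$loss
}

# Loss plus d(loss)/d(pred); shared by diceLoss() and the trainer.
diceLossGrad <- function(pred, truth, eps = 1e-6, wantGrad = TRUE) {
  if (is.matrix(pred)) {
    checkSameShape(pred, truth)
    pred <- array(pred, dim = c(dim(pred), 1, 1))
    truth <- array(truth, dim = dim(pred))
  }
  checkSameShape(pred, truth)
  if (anyNA(pred) || min(pred) < 0 || max(pred) > 1)
    stop("pred values must lie in [0, 1]")
  if (!all(truth == 0 | truth == 1)) stop("truth must be strictly binary (0/1)")
  d <- dim(pred); N <- d[4]; HW <- d[1] * d[2] * d[3]
  pm <- matrix(pred, nrow = HW, ncol = N)
  tm <- matrix(truth, nrow = HW, ncol = N)
  num <- 2 * colSums(pm * tm) + eps
  den <- colSums(tm * tm) + colSums(pm * pm) + eps
  if (any(den == 0))
    stop("both masks are empty with eps = 0: loss undefined; use eps > 0")
  loss <- mean(1 - num / den)
  if (!wantGrad) return(list(loss = loss))
  # d/dp_i [1 - num/den] = -(2 y_i * den - num * 2 p_i) / den^2, averaged over N
  g <- -(2 * sweep(tm, 2, den, `*`) - 2 * sweep(pm, 2, num, `*`)) /
    matrix(den^2, nrow = HW, ncol = N, byrow = TRUE) / N
  list(loss = loss, dpred = array(g, dim = d))
}

#' Binarize a probability map and compute all four metrics
#'
#' @param pred probability matrix in `[0, 1]`.
#' @param truth binary ground-truth matrix of the same size.
#' @param threshold binarization cut; pixels with `pred >= threshold` are
#'   labelled lesion.
#' @param standard use conventional recall for sensitivity (see
#'   [sensitivity()]).
#' @return A list with elements `sensitivity`, `specificity`, `dice`, `iou`
#'   and `counts` (a [ConfusionCounts-class]).
#' @export
evaluateSegmentation <- function(pred, truth, threshold = 0.5,
                                 standard = FALSE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (anyNA(pred) || min(pred) < 0 || max(pred) > 1)
    stop("pred values must lie in [0, 1]")
  bin <- (pred >= threshold) * 1
  cc <- confusionCounts(bin, truth)
  list(sensitivity = sensitivity(cc, standard = standard),
       specificity = specificity(cc),
       dice = diceCoefficient(cc),
       iou = iou(cc),
       counts = cc)
}

#' Format a metric report as flat key/value text
#'
#' One `name<TAB>value` line per metric, values to four decimals (the
#' reporting precision of the reference tables).
#'
#' @param report a list as returned by [evaluateSegmentation()] or any named
#'   list of scalar metrics.
#' @return Character vector of lines.
#' @export
formatMetricReport <- function(report) {
  vals <- report[vapply(report, function(x) is.numeric(x) && length(x) == 1,
                        logical(1))]
  sprintf("%s\t%.4f", names(vals), unlist(vals))
}

#' Write a metric report to a text file
#' @param report see [formatMetricReport()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  writeLines(formatMetricReport(report), path)
  invisible(path)
}
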