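# Overlap metrics for binary segmentation.

check_binary <- function(m, what = "mask") {
  v <- as.vector(m)
  if (!all(v %in% c(0, 1))) stop(what, " must be binary (0/1)")
  invisible(m)
}

#' Pixelwise confusion counts
#'
#' @param pred_mask,true_mask binary masks (0/1) of identical shape.
#' @return named numeric vector with `TP`, `FP`, `TN`, `FN`
#'   (sums to the pixel count).
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)) &&
      length(pred_mask) != length(true_mask)) {
    stop("mask shapes differ")
  }
  check_binary(pred_mask, "predicted mask")
  check_binary(true_mask, "true mask")
  p <- as.vector(pred_mask)
  t <- as.vector(true_mask)
  c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
    TN = sum(p == 0 & t == 0), FN = sum(p == 0 & t == 1))
}

#' Segmentation metrics from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/total, DSC = 2|G∩P|/(|G|+|P|) and
#' IoU = |G∩P|/|G∪P|. When a denominator is zero the conventional value is
#' returned and flagged: empty ground truth and empty prediction agree
#' perfectly (DSC = IoU = 1); an undefined precision (nothing predicted) is
#' 1 only if nothing was missed, and symmetrically for recall.
#'
#' @param counts output of [confusion_counts()] (or any named vector with
#'   `TP`, `FP`, `TN`, `FN`).
#' @return a `nodseg_metrics` list with the five metrics, the counts and a
#'   `degenerate` flag vector marking convention-valued entries.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  deg <- c(precision = FALSE, recall = FALSE, dsc = FALSE, iou = FALSE)
  precision <- if (tp + fp == 0) { deg["precision"] <- TRUE; as.numeric(fn == 0) } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { deg["recall"] <- TRUE; as.numeric(fp == 0) } else tp / (tp + fn)
  g <- tp + fn  # |G|
  p <- tp + fp  # |P|
  dsc <- if (g + p == 0) { deg["dsc"] <- TRUE; 1 } else 2 * tp / (g + p)
  iou <- if (tp + fp + fn == 0) { deg["iou"] <- TRUE; 1 } else tp / (tp + fp + fn)
  structure(list(precision = precision, recall = recall,
                 accuracy = (tp + tn) / total, dsc = dsc, iou = iou,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 degenerate = deg),
            class = "nodseg_metrics")
}

#' @export
print.nodseg_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f | recall %.4f | accuracy %.4f | DSC %.4f | IoU %.4f\n",
              x$precision, x$recall, x$accuracy, x$dsc, x$iou))
  invisible(x)
}

#' BCE-Dice loss
#'
#' Weighted sum of binary cross-entropy and the smoothed Dice loss
#' `1 - (2 sum(p t) + s) / (sum(p) + sum(t) + s)`.
#'
#' @param pred probability map, values in (0, 1).
#' @param target binary mask of the same shape.
#' @param w_bce,w_dice loss weights (must sum to 1).
#' @param smooth Dice smoothing constant `s`.
#' @return non-negative scalar loss.
#' @export
bce_dice_loss <- function(pred, target, w_bce = 0.5, w_dice = 0.5, smooth = 1.0) {
  if (length(pred) != length(target)) stop("pred/target shapes differ")
  if (abs(w_bce + w_dice - 1) > 1e-9) stop("loss weights must sum to 1")
  p <- pmin(pmax(as.vector(pred), 1e-7), 1 - 1e-7)
  t <- as.vector(target)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dice <- 1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
  w_bce * bce + w_dice * dice
}
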