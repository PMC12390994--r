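#' Pixel confusion counts for a binary mask pair
#'
#' The panicle class (value 1) is the positive class: `tp` are pixels
#' correctly classified as panicle, `fp` background pixels predicted as
#' panicle, `fn` panicle pixels predicted as background, `tn` background
#' pixels correctly left as background.
#'
#' @param pred,ref Binary matrices of equal shape (values in `{0, 1}`).
#' @return A list of class `confusion_counts` with integer elements `tp`,
#'   `fp`, `fn`, `tn`; the four always sum to the pixel count.
#' @export
confusion_counts <- function(pred, ref) {
  check_mask(pred, "pred")
  check_mask(ref, "ref")
  if (!all(dim(pred) == dim(ref))) abort("`pred` and `ref` shapes differ.")
  tp <- sum(pred == 1L & ref == 1L)
  fp <- sum(pred == 1L & ref == 0L)
  fn <- sum(pred == 0L & ref == 1L)
  tn <- sum(pred == 0L & ref == 0L)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' Segmentation quality metrics from confusion counts
#'
#' Computes pixel accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, the
#' panicle-class IoU `TP/(TP+FP+FN)`, the background-class IoU
#' `TN/(TN+FP+FN)`, and mIoU as the mean of the two class IoUs. A metric
#' whose denominator is zero is reported as 0 and its name recorded in the
#' `degenerate` list-column (with a warning).
#'
#' @param counts A `confusion_counts` object, or a binary `pred` matrix if
#'   `ref` is given.
#' @param ref Optional reference mask (convenience form).
#' @return One-row tibble with columns `pixel_accuracy`, `precision`,
#'   `recall`, `f1`, `iou_panicle`, `iou_background`, `miou`,
#'   `degenerate`.
#' @examples
#' seg_metrics(structure(list(tp = 8, fp = 2, fn = 2, tn = 88),
#'                       class = "confusion_counts"))
#' @export
seg_metrics <- function(counts, ref = NULL) {
  if (!is.null(ref)) counts <- confusion_counts(counts, ref)
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) abort("all confusion counts are zero.")
  degen <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      degen <<- c(degen, name)
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  out <- tibble(
    pixel_accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = f1,
    iou_panicle = safe_div(tp, tp + fp + fn, "iou_panicle"),
    iou_background = safe_div(tn, tn + fp + fn, "iou_background"),
    degenerate = list(degen)
  )
  out$miou <- (out$iou_panicle + out$iou_background) / 2
  if (length(degen) > 0) {
    warn(sprintf("zero-denominator metrics reported as 0: %s",
                 paste(degen, collapse = ", ")))
  }
  dplyr::relocate(out, "degenerate", .after = "miou")
}

#' Evaluate a set of mask pairs
#'
#' Micro aggregation sums confusion counts over all pairs and computes the
#' metrics once; macro aggregation averages per-image metrics. Which
#' convention a published table used is rarely stated, so both are
#' available and the result records the one applied.
#'
#' @param pred_masks,ref_masks Lists of binary matrices (pairwise equal
#'   shapes).
#' @param aggregation `"micro"` or `"macro"`.
#' @return One-row tibble of metrics plus columns `aggregation` and
#'   `n_images`.
#' @export
evaluate_masks <- function(pred_masks, ref_masks,
                           aggregation = c("micro", "macro")) {
  aggregation <- match.arg(aggregation)
  if (length(pred_masks) == 0L) abort("no mask pairs supplied.")
  if (length(pred_masks) != length(ref_masks)) {
    abort("`pred_masks` and `ref_masks` differ in length.")
  }
  counts <- map2(pred_masks, ref_masks, confusion_counts)
  if (aggregation == "micro") {
    total <- structure(
      list(tp = sum(map_dbl(counts, "tp")), fp = sum(map_dbl(counts, "fp")),
           fn = sum(map_dbl(counts, "fn")), tn = sum(map_dbl(counts, "tn"))),
      class = "confusion_counts"
    )
    res <- seg_metrics(total)
  } else {
    per <- map(counts, seg_metrics) |> list_rbind()
    num <- c("pixel_accuracy", "precision", "recall", "f1",
             "iou_panicle", "iou_background", "miou")
    res <- as_tibble(as.list(colMeans(per[num])))
    res$degenerate <- list(unique(unlist(per$degenerate)))
  }
  res$aggregation <- aggregation
  res$n_images <- length(pred_masks)
  res
}
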