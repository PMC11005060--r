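# Evaluation metrics: pixel confusion counts, IoU and Dice.

#' Confusion counts between a thresholded prediction and a binary mask
#'
#' Pixels with predicted probability >= `threshold` count as positive.
#'
#' @param pred probability map (any shape).
#' @param y binary mask, same shape.
#' @param threshold binarization threshold (default 0.5).
#' @return list with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, y, threshold = 0.5) {
  check_same_shape(y, pred, "confusion_counts")
  pb <- pred >= threshold
  yb <- y >= 0.5
  list(tp = sum(pb & yb), fp = sum(pb & !yb),
       fn = sum(!pb & yb), tn = sum(!pb & !yb))
}

#' Intersection-over-union from confusion counts
#'
#' IoU = TP / (TP + FN + FP).  When TP = FP = FN = 0 (empty ground truth and
#' empty prediction) the score is defined as 1.
#'
#' @param c confusion counts from [confusion_counts()].
#' @export
iou_score <- function(c) {
  den <- c$tp + c$fn + c$fp
  if (den == 0) 1.0 else c$tp / den
}

#' Dice coefficient from confusion counts
#'
#' Dice = 2 TP / (2 TP + FN + FP); equals 2 IoU / (1 + IoU).  Empty-vs-empty
#' scores 1.
#'
#' @inheritParams iou_score
#' @export
dice_score <- function(c) {
  den <- 2 * c$tp + c$fn + c$fp
  if (den == 0) 1.0 else 2 * c$tp / den
}

#' Per-image and aggregate segmentation metrics
#'
#' @param preds list of probability maps (or a (B,1,H,W) array).
#' @param masks list of binary masks (or a (B,1,H,W) array).
#' @param ids optional image identifiers.
#' @param threshold binarization threshold.
#' @param pooled if TRUE, also aggregate by pooling pixels across images
#'   rather than averaging per-image scores.
#' @return a `metrics_report`: data.frame `per_image` (image_id, iou, dice)
#'   plus aggregate means (`iou`, `dice`) and, when requested, pooled
#'   variants.
#' @export
metrics_report <- function(preds, masks, ids = NULL, threshold = 0.5,
                           pooled = FALSE) {
  as_list <- function(x) {
    if (is.array(x) && length(dim(x)) == 4)
      lapply(seq_len(dim(x)[1]), function(b) x[b, , , , drop = FALSE])
    else if (is.list(x)) x else list(x)
  }
  preds <- as_list(preds); masks <- as_list(masks)
  stopifnot(length(preds) == length(masks))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  cc <- mapply(function(p, m) confusion_counts(p, m, threshold),
               preds, masks, SIMPLIFY = FALSE)
  per <- data.frame(image_id = ids,
                    iou = vapply(cc, iou_score, numeric(1)),
                    dice = vapply(cc, dice_score, numeric(1)),
                    stringsAsFactors = FALSE)
  rep <- list(per_image = per, iou = mean(per$iou), dice = mean(per$dice))
  if (pooled) {
    tot <- list(tp = sum(vapply(cc, `[[`, numeric(1), "tp")),
                fp = sum(vapply(cc, `[[`, numeric(1), "fp")),
                fn = sum(vapply(cc, `[[`, numeric(1), "fn")),
                tn = sum(vapply(cc, `[[`, numeric(1), "tn")))
    rep$iou_pooled <- iou_score(tot)
    rep$dice_pooled <- dice_score(tot)
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("IoU %.4f  Dice %.4f  (mean over %d images)\n",
              x$iou, x$dice, nrow(x$per_image)))
  if (!is.null(x$iou_pooled))
    cat(sprintf("pooled: IoU %.4f  Dice %.4f\n", x$iou_pooled, x$dice_pooled))
  invisible(x)
}

#' Write a metrics report as CSV (per image) + JSON (aggregate)
#'
#' @param report a `metrics_report`.
#' @param csv_path,json_path output paths (NULL skips either).
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    agg <- report[setdiff(names(report), "per_image")]
    jsonlite::write_json(agg, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
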