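# Evaluation metrics: IoU, Dice, precision, recall, specificity from
# pixel-wise confusion counts, with per-image or pixel-pooled
# aggregation.

#' Pixel-wise confusion counts
#'
#' Foreground (value 1) is the positive class.
#'
#' @param pred_mask,G binary arrays of identical shape (any
#'   dimensionality; typically (batch, 1, H, W) or a matrix).
#' @return list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred_mask, G) {
  if (!identical(dim_or_len(pred_mask), dim_or_len(G)))
    stop("confusion_counts: prediction and ground truth shapes differ")
  check_binary(pred_mask, "prediction")
  check_binary(G, "ground truth")
  tp <- sum(pred_mask == 1 & G == 1)
  fp <- sum(pred_mask == 1 & G == 0)
  fn <- sum(pred_mask == 0 & G == 1)
  tn <- sum(pred_mask == 0 & G == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Segmentation scores from confusion counts
#'
#' IoU = tp/(tp+fp+fn), Dice = 2tp/(2tp+fp+fn), Precision = tp/(tp+fp),
#' Recall = tp/(tp+fn), Specificity = tn/(tn+fp).  A degenerate
#' denominator (e.g. empty ground truth and empty prediction) scores 1,
#' matching the smoothed-Dice convention.
#'
#' @param counts list from [confusion_counts()].
#' @return named list with `iou`, `dice`, `precision`, `recall`,
#'   `specificity`, all in \[0, 1\].
#' @export
segmentation_scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  list(iou = safe_ratio(tp, tp + fp + fn),
       dice = safe_ratio(2 * tp, 2 * tp + fp + fn),
       precision = safe_ratio(tp, tp + fp),
       recall = safe_ratio(tp, tp + fn),
       specificity = safe_ratio(tn, tn + fp))
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred binary prediction batch (batch, 1, H, W).
#' @param G binary ground-truth batch of the same shape.
#' @param aggregate `"per_image"` (mean of per-image scores, default)
#'   or `"pooled"` (counts pooled over all pixels first).
#' @param ids optional image identifiers for the per-image table.
#' @return a `metrics_report`: list with `summary` (named numeric),
#'   `per_image` (data.frame) and the aggregation mode.
#' @export
evaluate_masks <- function(pred, G, aggregate = c("per_image", "pooled"),
                           ids = NULL) {
  aggregate <- match.arg(aggregate)
  check_same_shape(pred, G)
  n <- dim(pred)[1L]
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    sc <- segmentation_scores(
      confusion_counts(pred[i, , , , drop = FALSE],
                       G[i, , , , drop = FALSE]))
    as.data.frame(c(list(id = ids[i]), sc))
  })
  per_image <- do.call(rbind, rows)
  summary <- if (aggregate == "per_image") {
    vapply(c("iou", "dice", "precision", "recall", "specificity"),
           function(k) mean(per_image[[k]]), numeric(1L))
  } else {
    cts <- confusion_counts(pred, G)
    unlist(segmentation_scores(cts))
  }
  structure(list(summary = summary, per_image = per_image,
                 aggregate = aggregate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics (%s aggregation, %d images)\n",
              x$aggregate, nrow(x$per_image)))
  print(round(x$summary, 4))
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' The CSV holds one row per image plus a summary row; the JSON holds
#' the summary keyed iou/dice/precision/recall/specificity.
#'
#' @param report a `metrics_report`.
#' @param csv,json output paths (either may be `NULL` to skip).
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    tab <- report$per_image
    sm <- as.data.frame(c(list(id = "summary"), as.list(report$summary)))
    utils::write.csv(rbind(tab, sm), csv, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(as.list(report$summary), json, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}
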