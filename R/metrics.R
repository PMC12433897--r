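#' Intersection-over-union of two boxes
#'
#' @param a,b Length-4 vectors `(x1, y1, x2, y2)` with `x2 >= x1`,
#'   `y2 >= y1`.
#' @return IoU in `[0, 1]` (0 for disjoint or degenerate boxes).
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

.check_records <- function(df, scored) {
  need <- c("image_id", "class_id", "x1", "y1", "x2", "y2")
  if (scored) need <- c(need, "score")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$x2 < df$x1) || any(df$y2 < df$y1)) {
    stop("boxes must satisfy x2 >= x1 and y2 >= y1", call. = FALSE)
  }
  df
}

# Greedy score-descending matching within one (image, class) group.
# Returns a logical TP flag per prediction row (in score order) and the
# number of matched ground truths.
.match_group <- function(preds, gts, iou_thr) {
  ord <- order(preds$score, decreasing = TRUE)
  used <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(preds))
  for (i in ord) {
    if (nrow(gts) == 0) break
    ious <- vapply(seq_len(nrow(gts)), function(j) {
      if (used[j]) -1 else box_iou(as.numeric(preds[i, c("x1", "y1", "x2", "y2")]),
                                   as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
    }, numeric(1))
    j <- which.max(ious)  # ties broken by lowest ground-truth index
    if (length(j) && ious[j] >= iou_thr) {
      used[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  list(tp = tp, matched = sum(used))
}

#' Match detections to ground truths
#'
#' Score-descending greedy matching per image and class at a fixed IoU
#' threshold: each ground truth is matched at most once, unmatched
#' predictions are false positives, unmatched ground truths false
#' negatives.
#'
#' @param preds Data frame with `image_id`, `class_id`, `score`,
#'   `x1`, `y1`, `x2`, `y2`.
#' @param gts Data frame with `image_id`, `class_id`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thr IoU threshold (default 0.5).
#' @return List with integer counts `tp`, `fp`, `fn`.
#' @export
match_detections <- function(preds, gts, iou_thr = 0.5) {
  preds <- .check_records(preds, scored = TRUE)
  gts <- .check_records(gts, scored = FALSE)
  keys <- unique(rbind(preds[, c("image_id", "class_id")],
                       gts[, c("image_id", "class_id")]))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (r in seq_len(nrow(keys))) {
    p <- preds[preds$image_id == keys$image_id[r] & preds$class_id == keys$class_id[r], ]
    g <- gts[gts$image_id == keys$image_id[r] & gts$class_id == keys$class_id[r], ]
    m <- .match_group(p, g, iou_thr)
    tp <- tp + m$matched
    fp <- fp + nrow(p) - m$matched
    fn <- fn + nrow(g) - m$matched
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; the undefined
#' `0/0` case is reported as 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return List with `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  list(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Average precision at a fixed IoU threshold
#'
#' All-point interpolated area under the precision-recall curve (the
#' modern detector-evaluation convention): predictions are ranked by score
#' across images, matched greedily, the precision envelope is made
#' monotone from the right, and the area is summed over recall increments.
#' Records are treated as one class.
#'
#' @param preds,gts Records as in [match_detections()].
#' @param iou_thr IoU threshold (default 0.5).
#' @return AP in `[0, 1]` (0 if there are no ground truths).
#' @export
average_precision <- function(preds, gts, iou_thr = 0.5) {
  preds <- .check_records(preds, scored = TRUE)
  gts <- .check_records(gts, scored = FALSE)
  n_gt <- nrow(gts)
  if (n_gt == 0) return(0)
  if (nrow(preds) == 0) return(0)
  tp_flags <- logical(0)
  scores <- numeric(0)
  for (img in unique(c(preds$image_id, gts$image_id))) {
    p <- preds[preds$image_id == img, ]
    g <- gts[gts$image_id == img, ]
    m <- .match_group(p, g, iou_thr)
    tp_flags <- c(tp_flags, m$tp)
    scores <- c(scores, p$score)
  }
  ord <- order(scores, decreasing = TRUE)
  tp_flags <- tp_flags[ord]
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  mrec <- c(0, rec)
  mpre <- c(1, prec)
  for (i in rev(seq_len(length(mpre) - 1))) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(diff(mrec) > 0)
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

#' Mean average precision over classes
#'
#' @param aps Numeric vector of per-class AP values.
#' @return Unweighted mean.
#' @export
mean_ap <- function(aps) mean(aps)

#' Full detection metrics
#'
#' Computes TP/FP/FN, precision, recall, per-class AP and their mean at one
#' IoU threshold. Classes present only in the predictions (no ground
#' truths) are excluded from the mAP with a warning.
#'
#' @inheritParams match_detections
#' @return Object of class `detection_metrics`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `ap_per_class` (named by class), `map`.
#' @export
detection_metrics <- function(preds, gts, iou_thr = 0.5) {
  preds <- .check_records(preds, scored = TRUE)
  gts <- .check_records(gts, scored = FALSE)
  counts <- match_detections(preds, gts, iou_thr)
  pr <- precision_recall(counts$tp, counts$fp, counts$fn)
  classes <- sort(unique(gts$class_id))
  orphan <- setdiff(unique(preds$class_id), classes)
  if (length(orphan)) {
    warning("classes with no ground truths excluded from mAP: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  aps <- vapply(classes, function(cl) {
    average_precision(preds[preds$class_id == cl, ], gts[gts$class_id == cl, ], iou_thr)
  }, numeric(1))
  names(aps) <- classes
  structure(c(counts, pr, list(ap_per_class = aps, map = mean_ap(aps))),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\nprecision %.4f  recall %.4f  mAP %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$map))
  invisible(x)
}
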