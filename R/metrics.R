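# Classification and weak-localization metrics: confusion-matrix summary
# statistics, box IoU, mean IoU over stone-containing images (a missed
# image contributes 0), and all-point interpolated average precision at a
# single IoU threshold with one detection per image.

#' Classification metrics
#'
#' Thresholds each record's score at `decision_threshold`, tabulates the
#' confusion matrix against the manifest labels and derives accuracy,
#' sensitivity, specificity and F1.  Degenerate denominators (e.g. no
#' positive labels) yield `NaN` with a warning.
#'
#' @param records list of detection records.
#' @param manifest `data.frame` with columns `image_id`, `label`.
#' @param decision_threshold score threshold; default 0.5.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `confusion` (TP/FP/TN/FN) and `n_images`.
#' @export
classification_metrics <- function(records, manifest,
                                   decision_threshold = 0.5) {
  scores <- stats::setNames(vapply(records, `[[`, numeric(1), "score"),
                            vapply(records, `[[`, character(1), "image_id"))
  missing <- setdiff(manifest$image_id, names(scores))
  if (length(missing))
    stop("no detection record for image(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  y <- manifest$label
  pred <- as.integer(scores[manifest$image_id] >= decision_threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  div <- function(a, b, what) {
    if (b == 0) { warning(what, " undefined: zero denominator",
                          call. = FALSE); return(NaN) }
    a / b
  }
  list(accuracy = div(tp + tn, length(y), "accuracy"),
       sensitivity = div(tp, tp + fn, "sensitivity"),
       specificity = div(tn, tn + fp, "specificity"),
       f1 = div(2 * tp, 2 * tp + fp + fn, "f1"),
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       n_images = length(y))
}

#' Intersection over union of two boxes
#'
#' Half-open pixel areas; symmetric; 1 for identical and 0 for disjoint
#' boxes.
#'
#' @param a,b [bounding_box()] objects.
#' @return fraction in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  iy <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_area(a) + box_area(b) - inter)
}

#' Mean IoU over stone-containing images
#'
#' Averages the per-image IoU between the predicted and ground-truth box
#' over every image that has a ground-truth box; an image with no predicted
#' box contributes 0, so missed detections are penalised.
#'
#' @param records list of detection records.
#' @param gt_boxes named list mapping image_id to [bounding_box()], covering
#'   all positive images.
#' @return fraction in `[0, 1]`.
#' @export
mean_iou <- function(records, gt_boxes) {
  if (length(gt_boxes) == 0) stop("gt_boxes is empty", call. = FALSE)
  by_id <- stats::setNames(records,
                           vapply(records, `[[`, character(1), "image_id"))
  ious <- vapply(names(gt_boxes), function(id) {
    r <- by_id[[id]]
    if (is.null(r) || is.null(r$box)) 0 else box_iou(r$box, gt_boxes[[id]])
  }, numeric(1))
  mean(ious)
}

#' Average precision of score-ranked detections
#'
#' One detection per image, ranked by classification score; a detection is
#' a true positive iff its IoU with the image's ground-truth box reaches
#' `iou_threshold`.  The precision-recall curve over all positive images is
#' integrated with all-point interpolation.
#'
#' @inheritParams mean_iou
#' @param iou_threshold IoU required for a match; default 0.5.
#' @return fraction in `[0, 1]`.
#' @export
average_precision <- function(records, gt_boxes, iou_threshold = 0.5) {
  n_pos <- length(gt_boxes)
  if (n_pos == 0) stop("gt_boxes is empty", call. = FALSE)
  dets <- Filter(function(r) !is.null(r$box), records)
  if (length(dets) == 0) return(0)
  ids <- vapply(dets, `[[`, character(1), "image_id")
  scores <- vapply(dets, `[[`, numeric(1), "score")
  ord <- order(-scores, ids)      # stable, deterministic
  hit <- vapply(ord, function(k) {
    id <- ids[k]
    !is.null(gt_boxes[[id]]) &&
      box_iou(dets[[k]]$box, gt_boxes[[id]]) >= iou_threshold
  }, logical(1))
  tp <- cumsum(hit)
  fp <- cumsum(!hit)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # all-point interpolation: precision envelope integrated over recall
  penv <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * penv)
}

#' Full evaluation report
#'
#' Combines [classification_metrics()], [mean_iou()] and
#' [average_precision()] into one report.
#'
#' @inheritParams classification_metrics
#' @inheritParams average_precision
#' @return list of class `mfadnet_metrics`.
#' @export
evaluate_detections <- function(records, manifest, gt_boxes,
                                decision_threshold = 0.5,
                                iou_threshold = 0.5) {
  pos_ids <- manifest$image_id[manifest$label == 1]
  missing_gt <- setdiff(pos_ids, names(gt_boxes))
  if (length(missing_gt))
    stop("ground-truth box missing for positive image(s): ",
         paste(missing_gt, collapse = ", "), call. = FALSE)
  rep <- classification_metrics(records, manifest, decision_threshold)
  gt <- gt_boxes[intersect(names(gt_boxes), pos_ids)]
  if (length(gt)) {
    rep$miou <- mean_iou(records, gt)
    rep$ap <- average_precision(records, gt, iou_threshold)
  } else {
    rep$miou <- NaN
    rep$ap <- NaN
  }
  class(rep) <- "mfadnet_metrics"
  rep
}

#' @export
print.mfadnet_metrics <- function(x, ...) {
  cat("Classification (n =", x$n_images, "images)\n")
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f  f1 %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1))
  cat("  confusion: ", paste(names(x$confusion), x$confusion,
                             collapse = "  "), "\n")
  if (!is.null(x$miou))
    cat(sprintf("Localization: mIoU %.4f  AP %.4f\n", x$miou, x$ap))
  invisible(x)
}
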