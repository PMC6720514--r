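#' Object-level evaluation of kernel detections
#'
#' Detections are compared with ground-truth annotations at a minimum
#' intersection-over-union. Only one detection can claim a given ground
#' truth — the one with the highest IoU — and any further detections
#' overlapping it above the threshold count as false positives.
#'
#' @name detection_eval
#' @keywords internal
NULL

instance_iou <- function(gt, det, mode) {
  if (mode == "mask") {
    if (is.null(gt$polygon) || is.null(det$polygon))
      stopf("mode = \"mask\" requires polygons on both sides")
    # masks live inside their boxes: disjoint boxes => disjoint masks
    if (box_iou(gt$box, det$box) == 0) return(0)
    mask_iou(gt$polygon, det$polygon)
  } else {
    box_iou(gt$box, det$box)
  }
}

#' Match detections to ground truth at an IoU threshold
#'
#' Detections are processed in descending score order (score ties broken
#' by higher best IoU, then stable input order); each is assigned to the
#' unmatched ground truth with the highest IoU if that IoU reaches the
#' threshold (true positive), otherwise it is a false positive.
#' Unmatched ground truths are false negatives.
#'
#' @param gt,det Lists of [kernel_instance()] (ground truth, detections).
#' @param iou_threshold Minimum IoU for a true positive. Default 0.5.
#' @param mode `"box"` (axis-aligned box IoU) or `"mask"` (rasterized
#'   polygon IoU; requires polygons on both sides).
#' @return A list of class `kps_match` with `tp_pairs` (data frame of
#'   `gt`, `det` indices and `iou`), `fp_det`, `fn_gt` (indices), and
#'   `iou_threshold`.
#' @export
match_detections <- function(gt, det, iou_threshold = 0.5,
                             mode = c("box", "mask")) {
  mode <- match.arg(mode)
  ng <- length(gt); nd <- length(det)
  iou <- matrix(0, nrow = ng, ncol = nd)
  if (ng > 0L && nd > 0L)
    for (i in seq_len(ng)) for (j in seq_len(nd))
      iou[i, j] <- instance_iou(gt[[i]], det[[j]], mode)
  scores <- vapply(det, function(d) d$score, numeric(1L))
  scores[is.na(scores)] <- 1
  best_iou <- if (ng > 0L && nd > 0L) apply(iou, 2L, max) else rep(0, nd)
  ord <- order(-scores, -best_iou, seq_len(nd))
  taken <- rep(FALSE, ng)
  tp <- list()
  fp <- integer()
  for (j in ord) {
    cand <- if (ng > 0L) iou[, j] else numeric()
    cand[taken] <- -1
    if (length(cand) > 0L && max(cand) >= iou_threshold) {
      i <- which.max(cand)
      taken[i] <- TRUE
      tp[[length(tp) + 1L]] <- c(gt = i, det = j, iou = iou[i, j])
    } else {
      fp <- c(fp, j)
    }
  }
  tp_pairs <- if (length(tp)) as.data.frame(do.call(rbind, tp))
              else data.frame(gt = integer(), det = integer(), iou = numeric())
  structure(list(tp_pairs = tp_pairs, fp_det = sort(fp),
                 fn_gt = which(!taken), iou_threshold = iou_threshold),
            class = "kps_match")
}

#' Precision, recall and F1 from a match result
#'
#' Precision = TP / (TP + FP), recall = TP / P (all ground truths), and
#' F1 = 2 TP / (2 TP + FP + FN), each reported as a percentage. With no
#' detections, precision is 0 by convention; with no ground truth,
#' recall is `NA` (flagged, not silently 0).
#'
#' @param m A `kps_match`.
#' @return Named numeric `c(precision, recall, f1)` in percent.
#' @export
precision_recall_f1 <- function(m) {
  tp <- nrow(m$tp_pairs); fp <- length(m$fp_det); fn <- length(m$fn_gt)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  c(precision = 100 * precision, recall = 100 * recall, f1 = 100 * f1)
}

#' 11-point interpolated average precision
#'
#' Detections from all images are pooled and swept in descending score
#' order, accumulating true/false positives under the per-image matching
#' rule. The precision-recall curve is interpolated at the 11 recall
#' levels 0, 0.1, ..., 1 by the maximum precision at any recall at or
#' above each level, and the mean of the 11 interpolated values is the
#' AP (the PASCAL VOC convention).
#'
#' @param gt_by_image,det_by_image Lists of `kps_image` paired by
#'   `image_id`.
#' @inheritParams match_detections
#' @return AP as a percentage.
#' @export
average_precision <- function(gt_by_image, det_by_image, iou_threshold = 0.5,
                              mode = c("box", "mask")) {
  mode <- match.arg(mode)
  gt_ids <- vapply(gt_by_image, function(x) as.character(x$image_id), character(1L))
  det_ids <- vapply(det_by_image, function(x) as.character(x$image_id), character(1L))
  n_gt <- sum(lengths(lapply(gt_by_image, `[[`, "instances")))
  if (n_gt == 0L) return(0)
  # pooled ranked detection list
  pool <- do.call(rbind, lapply(seq_along(det_by_image), function(k) {
    insts <- det_by_image[[k]]$instances
    if (length(insts) == 0L) return(NULL)
    s <- vapply(insts, function(d) d$score, numeric(1L))
    if (anyNA(s)) stopf("average_precision: unscored detection in image %s",
                        det_by_image[[k]]$image_id)
    data.frame(img = det_ids[k], idx = seq_along(insts), score = s)
  }))
  if (is.null(pool) || nrow(pool) == 0L) return(0)
  pool <- pool[order(-pool$score), , drop = FALSE]
  taken <- lapply(gt_by_image, function(x) rep(FALSE, length(x$instances)))
  names(taken) <- gt_ids
  is_tp <- logical(nrow(pool))
  for (r in seq_len(nrow(pool))) {
    img <- pool$img[r]
    d <- det_by_image[[match(img, det_ids)]]$instances[[pool$idx[r]]]
    k <- match(img, gt_ids)
    g <- if (is.na(k)) list() else gt_by_image[[k]]$instances
    if (length(g) > 0L) {
      ious <- vapply(g, function(gi) instance_iou(gi, d, mode), numeric(1L))
      ious[taken[[img]]] <- -1
      if (max(ious) >= iou_threshold) {
        i <- which.max(ious)
        taken[[img]][i] <- TRUE
        is_tp[r] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  rec <- cum_tp / n_gt
  prec <- cum_tp / (cum_tp + cum_fp)
  levels <- seq(0, 1, by = 0.1)
  interp <- vapply(levels, function(r0) {
    ok <- rec >= r0
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1L))
  100 * mean(interp)
}

#' Evaluate a detection set against annotations
#'
#' Aggregates the object-level metrics over a dataset: precision, recall
#' and F1 from the pooled TP/FP/FN counts (detections optionally
#' filtered by a score threshold first), and the 11-point AP from the
#' full ranked detection list.
#'
#' @param annotations,detections Lists of `kps_image` paired by
#'   `image_id`.
#' @param score_threshold Minimum detection score entering the
#'   precision/recall/F1 counts; `NULL` (default) keeps all detections.
#'   AP always uses the full ranked list.
#' @inheritParams match_detections
#' @return A list of class `kps_metrics`: `precision`, `recall`, `f1`,
#'   `ap` (percent), counts `tp`, `fp`, `fn`, and `mode`.
#' @export
evaluate_dataset <- function(annotations, detections, iou_threshold = 0.5,
                             mode = c("box", "mask"), score_threshold = NULL) {
  mode <- match.arg(mode)
  ann_ids <- vapply(annotations, function(x) as.character(x$image_id), character(1L))
  tp <- fp <- fn <- 0L
  for (d in detections) {
    insts <- d$instances
    if (!is.null(score_threshold)) {
      s <- vapply(insts, function(i) i$score, numeric(1L))
      insts <- insts[is.na(s) | s >= score_threshold]
    }
    k <- match(as.character(d$image_id), ann_ids)
    g <- if (is.na(k)) list() else annotations[[k]]$instances
    m <- match_detections(g, insts, iou_threshold, mode)
    tp <- tp + nrow(m$tp_pairs)
    fp <- fp + length(m$fp_det)
    fn <- fn + length(m$fn_gt)
  }
  # annotated images with no detection record: all ground truths missed
  det_ids <- vapply(detections, function(x) as.character(x$image_id), character(1L))
  for (a in annotations[!(ann_ids %in% det_ids)])
    fn <- fn + length(a$instances)
  precision <- if (tp + fp == 0L) 0 else 100 * tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn == 0L) 0 else 100 * 2 * tp / (2 * tp + fp + fn)
  ap <- average_precision(annotations, detections, iou_threshold, mode)
  structure(list(precision = precision, recall = recall, f1 = f1, ap = ap,
                 tp = tp, fp = fp, fn = fn, mode = mode,
                 iou_threshold = iou_threshold),
            class = "kps_metrics")
}

#' @export
print.kps_metrics <- function(x, ...) {
  cat(sprintf(
    "detection metrics (%s IoU >= %.2f): AP %.1f | precision %.1f | recall %s | F1 %.1f  [TP %d, FP %d, FN %d]\n",
    x$mode, x$iou_threshold, x$ap, x$precision,
    if (is.na(x$recall)) "NA" else sprintf("%.1f", x$recall), x$f1,
    x$tp, x$fp, x$fn))
  invisible(x)
}
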