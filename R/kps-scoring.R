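#' Kernel fragment size in millimetres
#'
#' Sizes one instance by the rule matching its localisation granularity:
#' `"rotated_minor"` takes the minor axis of the minimum-area rotated
#' rectangle fitted to the polygon (masks and annotations);
#' `"aabb_shortest"` takes the shorter side of the axis-aligned bounding
#' box (box-only detections, which can only over-estimate the true
#' minor axis). The shortest diameter is the size that governs passage
#' through the 4.75 mm sieve screen of the laboratory protocol, because
#' the sieve shaking separates particles by their shortest dimension.
#'
#' @param inst A [kernel_instance()].
#' @param mode `"rotated_minor"` or `"aabb_shortest"`.
#' @param px_per_mm Pixels per millimetre (default 20).
#' @return Size in millimetres.
#' @export
instance_size_mm <- function(inst, mode = c("rotated_minor", "aabb_shortest"),
                             px_per_mm = 20) {
  mode <- match.arg(mode)
  if (mode == "rotated_minor") {
    if (is.null(inst$polygon))
      stopf("mode = \"rotated_minor\" requires a polygon (instance %s has none)",
            inst$id %||% "?")
    px_to_mm(min_area_rect(inst$polygon)$side_b, px_per_mm)
  } else {
    b <- inst$box
    px_to_mm(min(b[3L] - b[1L], b[4L] - b[2L]), px_per_mm)
  }
}

#' Kernel Processing Score
#'
#' The KPS of a set of fragments is the percentage whose size is
#' strictly below the sieve threshold (default 4.75 mm); a fragment at
#' exactly the threshold is over-size, i.e. not optimally processed.
#'
#' @param instances List of [kernel_instance()].
#' @inheritParams instance_size_mm
#' @param threshold_mm Sieve size in millimetres. Default 4.75.
#' @param score_threshold Minimum detection score for an instance to be
#'   counted; `NULL` keeps all. Annotation instances (no score) always
#'   count.
#' @return A list of class `kps_result`: `kps_percent`, counts
#'   `n_below` / `n_total`, `threshold_mm`, `size_mode`,
#'   `score_threshold`.
#' @export
kps <- function(instances, mode = c("rotated_minor", "aabb_shortest"),
                px_per_mm = 20, threshold_mm = 4.75, score_threshold = NULL) {
  mode <- match.arg(mode)
  if (!is.null(score_threshold)) {
    s <- vapply(instances, function(i) i$score, numeric(1L))
    instances <- instances[is.na(s) | s >= score_threshold]
  }
  n <- length(instances)
  if (n == 0L) stopf("KPS undefined: no instances after score filtering")
  sizes <- vapply(instances, instance_size_mm, numeric(1L),
                  mode = mode, px_per_mm = px_per_mm)
  n_below <- sum(sizes < threshold_mm)
  structure(list(kps_percent = 100 * n_below / n, n_below = n_below,
                 n_total = n, threshold_mm = threshold_mm, size_mode = mode,
                 score_threshold = score_threshold),
            class = "kps_result")
}

#' @export
print.kps_result <- function(x, ...) {
  cat(sprintf("KPS %.1f%% (%d of %d fragments < %.2f mm, %s)\n",
              x$kps_percent, x$n_below, x$n_total, x$threshold_mm,
              x$size_mode))
  invisible(x)
}

#' Per-sequence KPS for one or more models
#'
#' A sequence is the set of images captured at one processor-gap
#' setting. Instances are pooled across all images of the sequence
#' before the percentage is taken (one sample-size-weighted KPS per
#' sequence per model), never averaged image-by-image.
#'
#' @param seq A [sequence_record()] of annotated images.
#' @param detections_by_model Named list; each element is a list of
#'   `kps_image` detection records for this sequence's images. May be
#'   `NULL` to score annotations only.
#' @param mode_by_model Named character vector of size modes per model
#'   (see [instance_size_mm()]); unnamed scalar recycles to all models.
#' @inheritParams kps
#' @param annotation_mode Size mode for the annotation column.
#' @return One-row data frame: `sequence_id`, `pg`, `n_instances`, one
#'   KPS column per model, and `annotation`.
#' @export
sequence_kps <- function(seq, detections_by_model = NULL,
                         mode_by_model = "rotated_minor", px_per_mm = 20,
                         threshold_mm = 4.75, score_threshold = 0.5,
                         annotation_mode = "rotated_minor") {
  stopifnot(inherits(seq, "kps_sequence"))
  ann <- kps(all_instances(seq), mode = annotation_mode,
             px_per_mm = px_per_mm, threshold_mm = threshold_mm)
  row <- data.frame(sequence_id = seq$sequence_id, pg = seq$pg,
                    n_instances = ann$n_total)
  models <- names(detections_by_model)
  if (length(detections_by_model) > 0L) {
    modes <- if (is.null(names(mode_by_model)))
      stats::setNames(rep(mode_by_model, length.out = length(models)), models)
    else mode_by_model
    for (m in models) {
      insts <- all_instances(detections_by_model[[m]])
      r <- tryCatch(
        kps(insts, mode = modes[[m]], px_per_mm = px_per_mm,
            threshold_mm = threshold_mm, score_threshold = score_threshold),
        error = function(e) NULL)
      if (is.null(r))
        stopf("sequence %s: model %s has no scorable instances",
              seq$sequence_id, m)
      row[[m]] <- r$kps_percent
    }
  }
  row$annotation <- ann$kps_percent
  row
}

#' KPS table across sequences
#'
#' Applies [sequence_kps()] to each sequence, producing one row per
#' processor-gap sequence with per-model KPS columns and the annotation
#' KPS — the shape in which fragmentation results are reported across
#' processor gaps.
#'
#' @param sequences List of [sequence_record()].
#' @param detections_by_model Named list of per-model detections; each
#'   element is a list (parallel to `sequences`) of detection image
#'   lists.
#' @inheritParams sequence_kps
#' @return Data frame with one row per sequence.
#' @export
kps_table <- function(sequences, detections_by_model = NULL,
                      mode_by_model = "rotated_minor", px_per_mm = 20,
                      threshold_mm = 4.75, score_threshold = 0.5,
                      annotation_mode = "rotated_minor") {
  rows <- lapply(seq_along(sequences), function(k) {
    dets <- if (is.null(detections_by_model)) NULL
            else lapply(detections_by_model, `[[`, k)
    sequence_kps(sequences[[k]], dets, mode_by_model, px_per_mm,
                 threshold_mm, score_threshold, annotation_mode)
  })
  do.call(rbind, rows)
}

#' Average absolute KPS error of a model against annotations
#'
#' Mean over sequences of |model KPS - annotation KPS|, the summary
#' printed in the final row of a per-sequence KPS table.
#'
#' @param model_kps,annotation_kps Equal-length numeric vectors of KPS
#'   percentages, paired by sequence.
#' @return Mean absolute error in percentage points.
#' @export
average_absolute_error <- function(model_kps, annotation_kps) {
  if (length(model_kps) != length(annotation_kps))
    stopf("model and annotation KPS vectors differ in length (%d vs %d)",
          length(model_kps), length(annotation_kps))
  if (length(model_kps) < 1L) stopf("need at least one sequence")
  mean(abs(model_kps - annotation_kps))
}
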