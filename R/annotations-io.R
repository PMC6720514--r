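#' Kernel fragment instances and image records
#'
#' An instance is one kernel fragment: a polygon outline (annotation or
#' predicted mask) and/or an axis-aligned box, with an optional detector
#' confidence score. When a polygon is present the box is always derived
#' from it, so the two never disagree.
#'
#' @param polygon Two-column vertex matrix in pixels, or `NULL` for
#'   box-only detections.
#' @param box `c(xmin, ymin, xmax, ymax)` in pixels; ignored (recomputed)
#'   when `polygon` is given.
#' @param score Detector confidence in `[0, 1]`, or `NA` for annotations.
#' @param id Optional annotation/detection id.
#' @return A list of class `kps_instance`.
#' @export
kernel_instance <- function(polygon = NULL, box = NULL, score = NA_real_,
                            id = NULL) {
  if (is.null(polygon) && is.null(box))
    stopf("instance needs a polygon or a box")
  if (!is.null(polygon)) {
    polygon <- as_polygon(polygon)
    box <- box_from_polygon(polygon)
  } else {
    box <- as_box(box)
  }
  score <- as.numeric(score)
  if (!is.na(score) && (score < 0 || score > 1))
    stopf("score must be in [0, 1]")
  structure(list(id = id, polygon = polygon, box = box, score = score,
                 category = "kernel"),
            class = "kps_instance")
}

#' @rdname kernel_instance
#' @param image_id Image identifier (string or number).
#' @param width,height Image size in pixels.
#' @param px_per_mm Pixels per millimetre for this image (default 20).
#' @param pg Processor gap in mm (optional; `NA` when unknown).
#' @param year Harvest year (optional).
#' @param instances List of `kps_instance`.
#' @export
image_record <- function(image_id, width, height, instances = list(),
                         px_per_mm = 20, pg = NA_real_, year = NA_real_) {
  if (width <= 0 || height <= 0) stopf("image width and height must be positive")
  for (inst in instances) {
    b <- inst$box
    if (b[1L] < 0 || b[2L] < 0 || b[3L] > width || b[4L] > height)
      stopf("instance %s outside image bounds [0,%g]x[0,%g]",
            inst$id %||% "?", width, height)
  }
  structure(list(image_id = image_id, width = width, height = height,
                 px_per_mm = px_per_mm, pg = pg, year = year,
                 instances = instances),
            class = "kps_image")
}

#' @rdname kernel_instance
#' @param sequence_id Sequence identifier.
#' @param images Non-empty list of `kps_image`, all sharing this
#'   sequence's processor gap.
#' @export
sequence_record <- function(sequence_id, pg, images) {
  if (length(images) == 0L) stopf("sequence %s has no images", sequence_id)
  pgs <- vapply(images, function(im) as.numeric(im$pg), numeric(1L))
  if (any(!is.na(pgs) & pgs != pg))
    stopf("sequence %s: images carry a different processor gap", sequence_id)
  structure(list(sequence_id = sequence_id, pg = pg, images = images),
            class = "kps_sequence")
}

all_instances <- function(x) {
  if (inherits(x, "kps_sequence")) x <- x$images
  if (inherits(x, "kps_image")) x <- list(x)
  unlist(lapply(x, `[[`, "instances"), recursive = FALSE)
}

#' Read a COCO-style instance dataset
#'
#' Parses a COCO-style JSON file (`images`, `annotations` with polygon
#' `segmentation` and/or `bbox`, optional `score`; per-image custom
#' fields `px_per_mm`, `pg`, `year`) into validated image records.
#' On-disk boxes use the COCO `x, y, w, h` dialect; internally boxes are
#' corner-based `c(xmin, ymin, xmax, ymax)`.
#'
#' @param path Path to a JSON file.
#' @return A list of `kps_image` records, one per `images` entry.
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("malformed JSON in %s: %s",
                                            path, conditionMessage(e)))
  anns_by_img <- split(
    doc$annotations %||% list(),
    vapply(doc$annotations %||% list(), function(a) as.character(a$image_id),
           character(1L))
  )
  lapply(doc$images %||% list(), function(im) {
    ppm <- im$px_per_mm
    if (is.null(ppm)) {
      message(sprintf("image %s: no px_per_mm field, assuming default 20 px/mm",
                      im$id))
      ppm <- 20
    }
    anns <- anns_by_img[[as.character(im$id)]] %||% list()
    instances <- lapply(anns, function(a) {
      poly <- NULL
      seg <- a$segmentation
      if (!is.null(seg) && length(seg) > 0L) {
        flat <- unlist(seg[[1L]])
        if (length(flat) < 6L)
          stopf("annotation %s: polygon has fewer than 3 points",
                a$id %||% "?")
        poly <- matrix(flat, ncol = 2L, byrow = TRUE)
      }
      box <- NULL
      if (is.null(poly)) {
        bb <- unlist(a$bbox)
        if (length(bb) != 4L)
          stopf("annotation %s: neither polygon nor valid bbox", a$id %||% "?")
        box <- c(bb[1L], bb[2L], bb[1L] + bb[3L], bb[2L] + bb[4L])
      }
      tryCatch(
        kernel_instance(polygon = poly, box = box,
                        score = field_or_na(a, "score"), id = a$id),
        error = function(e) stopf("annotation %s: %s", a$id %||% "?",
                                  conditionMessage(e))
      )
    })
    image_record(image_id = im$id, width = im$width, height = im$height,
                 instances = instances, px_per_mm = ppm,
                 pg = field_or_na(im, "pg"), year = field_or_na(im, "year"))
  })
}

#' Write image records as COCO-style JSON
#'
#' Inverse of [read_dataset()]: boxes are serialized in the COCO
#' `x, y, w, h` dialect, polygons as flat `x1, y1, x2, y2, ...`
#' segmentation lists, and scores at full float precision.
#'
#' @param records List of `kps_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  next_id <- 0L
  anns <- list()
  imgs <- lapply(records, function(im) {
    out <- list(id = im$image_id, width = im$width, height = im$height,
                px_per_mm = im$px_per_mm)
    if (!is.na(im$pg)) out$pg <- im$pg
    if (!is.na(im$year)) out$year <- im$year
    out
  })
  for (im in records) {
    for (inst in im$instances) {
      next_id <- next_id + 1L
      b <- inst$box
      a <- list(id = inst$id %||% next_id, image_id = im$image_id,
                category_id = 1L,
                bbox = c(b[1L], b[2L], b[3L] - b[1L], b[4L] - b[2L]))
      if (!is.null(inst$polygon))
        a$segmentation <- list(as.numeric(t(inst$polygon)))
      if (!is.na(inst$score)) a$score <- inst$score
      anns[[length(anns) + 1L]] <- a
    }
  }
  doc <- list(images = imgs, annotations = anns,
              categories = list(list(id = 1L, name = "kernel")))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) stopf("cannot write %s: %s", path,
                                           conditionMessage(e)))
  invisible(path)
}

#' Write a CSV report
#'
#' @param rows A data frame.
#' @param path Output path; written with a header row, no row names.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  tryCatch(utils::write.csv(rows, path, row.names = FALSE),
           error = function(e) stopf("cannot write %s: %s", path,
                                     conditionMessage(e)))
  invisible(path)
}

#' Split a dataset into train and test images
#'
#' Random partition at the image level (never by instance, so no
#' instance of one image can leak across the split). The harvest
#' datasets behind this tool were split roughly 60/40.
#'
#' @param records List of `kps_image`.
#' @param train_fraction Fraction of images in the train split, in (0, 1).
#' @param seed Optional integer for a reproducible split.
#' @param stratify_by_pg Stratify the draw within each processor-gap
#'   level (off by default: the split is uniform at random).
#' @return `list(train = ..., test = ...)`, a disjoint partition with
#'   `round(train_fraction * n)` train images.
#' @export
split_dataset <- function(records, train_fraction = 0.6, seed = NULL,
                          stratify_by_pg = FALSE) {
  n <- length(records)
  if (n < 2L) stopf("need at least 2 images to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  idx <- with_seed(seed, {
    if (stratify_by_pg) {
      pg <- vapply(records, function(r) as.numeric(r$pg), numeric(1L))
      grp <- split(seq_len(n), factor(pg, exclude = NULL))
      sort(unlist(lapply(grp, function(g)
        sample(g, round(train_fraction * length(g))))))
    } else {
      sort(sample.int(n, round(train_fraction * n)))
    }
  })
  list(train = records[idx], test = records[setdiff(seq_len(n), idx)])
}
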