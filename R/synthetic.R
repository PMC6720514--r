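#' Configuration for the synthetic kernel dataset generator
#'
#' The generator emulates the statistical structure of annotated silage
#' image sequences: per processor-gap (PG) sequences of images, each
#' containing convex kernel-fragment polygons whose minor-axis sizes
#' follow a right-skewed lognormal law whose location increases with the
#' PG (a larger mill-roll gap leaves larger fragments). Fragment shapes
#' are polygonized ellipses, which keeps the true minor axis analytic.
#'
#' @param n_sequences Number of PG sequences.
#' @param pgs Processor-gap values (mm) cycled over the sequences.
#' @param images_per_sequence Images per sequence.
#' @param instances_per_image Mean fragment count per image (Poisson).
#' @param mu_log Function pg -> mean of log minor-axis (mm). The default
#'   `log(1.8 + 0.55 * pg)` spans annotation KPS from roughly 92% at
#'   PG 1 mm down to 69% at PG 3.5 mm at the default `sigma_log`.
#' @param sigma_log SD of log minor-axis (mm).
#' @param aspect_range Range of major/minor aspect ratios.
#' @param n_vertices_range Range of polygon vertex counts.
#' @param image_size `c(width, height)` in pixels.
#' @param px_per_mm Pixels per millimetre (default 20).
#' @param seed Integer seed; every random choice flows from it.
#' @return A list of class `kps_synth_config`.
#' @export
synthetic_config <- function(n_sequences = 17,
                             pgs = c(1, 2, 3, 3.5),
                             images_per_sequence = 5,
                             instances_per_image = 8,
                             mu_log = function(pg) log(1.8 + 0.55 * pg),
                             sigma_log = 0.5,
                             aspect_range = c(1.2, 2.5),
                             n_vertices_range = c(12L, 16L),
                             image_size = c(1000, 600),
                             px_per_mm = 20,
                             seed = 1L) {
  stopifnot(n_sequences >= 0, images_per_sequence > 0,
            instances_per_image > 0, sigma_log > 0,
            all(aspect_range >= 1), n_vertices_range[1L] >= 8L,
            all(image_size > 0), px_per_mm > 0)
  if (is.unsorted(pgs)) stopf("pgs must be sorted ascending")
  structure(list(n_sequences = n_sequences, pgs = pgs,
                 images_per_sequence = images_per_sequence,
                 instances_per_image = instances_per_image,
                 mu_log = mu_log, sigma_log = sigma_log,
                 aspect_range = aspect_range,
                 n_vertices_range = n_vertices_range,
                 image_size = image_size, px_per_mm = px_per_mm,
                 seed = seed),
            class = "kps_synth_config")
}

#' Lognormal location giving a target sub-threshold probability
#'
#' Returns the `mu_log` for which a lognormal(`mu`, `sigma`) minor-axis
#' law has `P(size < threshold_mm) = p`, useful for calibrating the
#' generator to a known expected KPS.
#'
#' @param p Target probability in (0, 1).
#' @param sigma_log Lognormal shape.
#' @param threshold_mm Sieve threshold (default 4.75 mm).
#' @return The `mu_log` value.
#' @export
mu_log_for_kps <- function(p, sigma_log = 0.5, threshold_mm = 4.75) {
  stopifnot(p > 0, p < 1, sigma_log > 0, threshold_mm > 0)
  log(threshold_mm) - sigma_log * stats::qnorm(p)
}

# One polygonized-ellipse fragment. The polygon is rescaled about its
# center so that its min-area-rect minor axis equals `minor_px` exactly,
# making the sampled size recoverable without polygonization error.
make_fragment_polygon <- function(minor_px, aspect, angle_rad, n_vertices,
                                  center) {
  a <- minor_px * aspect / 2   # semi-major
  b <- minor_px / 2            # semi-minor
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  th <- th + stats::runif(1L, 0, 2 * pi / n_vertices)
  ex <- a * cos(th); ey <- b * sin(th)
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  poly <- cbind(ex * ca - ey * sa, ex * sa + ey * ca)
  got <- min_area_rect(poly)$side_b
  poly <- poly * (minor_px / got)
  poly + rep(center, each = nrow(poly))
}

#' Generate a synthetic annotated dataset
#'
#' Produces sequences of images populated with convex kernel-fragment
#' polygons. Minor axes (mm) are drawn from the config's PG-dependent
#' lognormal law; each polygon's true minor axis is stored as
#' generation metadata (attribute `true_minor_mm` on each instance's
#' polygon, and column-wise in attribute `truth` of the result) for
#' recovery tests. Deterministic given `cfg$seed`; each sequence uses
#' its own derived seed, so regenerating any one sequence in isolation
#' reproduces it.
#'
#' @param cfg A [synthetic_config()].
#' @param max_retries Placement retries before giving up on an instance.
#' @return List of [sequence_record()] with attribute `truth` (data
#'   frame of `sequence_id`, `image_id`, `instance`, `minor_mm`).
#' @export
generate_dataset <- function(cfg, max_retries = 50L) {
  stopifnot(inherits(cfg, "kps_synth_config"))
  if (cfg$n_sequences == 0L) return(list())
  W <- cfg$image_size[1L]; H <- cfg$image_size[2L]
  truth <- list()
  seqs <- lapply(seq_len(cfg$n_sequences), function(s) {
    pg <- cfg$pgs[((s - 1L) %% length(cfg$pgs)) + 1L]
    mu <- cfg$mu_log(pg)
    with_seed(cfg$seed + 10007L * s, {
      images <- lapply(seq_len(cfg$images_per_sequence), function(i) {
        n_inst <- max(1L, stats::rpois(1L, cfg$instances_per_image))
        instances <- vector("list", n_inst)
        minors <- numeric(n_inst)
        for (k in seq_len(n_inst)) {
          placed <- FALSE
          for (try in seq_len(max_retries)) {
            minor_mm <- stats::rlnorm(1L, mu, cfg$sigma_log)
            minor_px <- minor_mm * cfg$px_per_mm
            aspect <- stats::runif(1L, cfg$aspect_range[1L], cfg$aspect_range[2L])
            half <- minor_px * aspect / 2 + 1
            if (2 * half >= min(W, H)) next
            ctr <- c(stats::runif(1L, half, W - half),
                     stats::runif(1L, half, H - half))
            nv <- sample(seq(cfg$n_vertices_range[1L],
                             cfg$n_vertices_range[2L]), 1L)
            poly <- make_fragment_polygon(minor_px, aspect,
                                          stats::runif(1L, 0, pi), nv, ctr)
            if (any(poly[, 1L] < 0 | poly[, 1L] > W |
                    poly[, 2L] < 0 | poly[, 2L] > H)) next
            attr(poly, "true_minor_mm") <- minor_mm
            instances[[k]] <- kernel_instance(polygon = poly,
                                              id = sprintf("s%d_i%d_k%d", s, i, k))
            attr(instances[[k]]$polygon, "true_minor_mm") <- minor_mm
            minors[k] <- minor_mm
            placed <- TRUE
            break
          }
          if (!placed)
            stopf("could not place instance (sequence %d image %d): fragments too large for the image", s, i)
        }
        truth[[length(truth) + 1L]] <<- data.frame(
          sequence_id = sprintf("seq%02d", s),
          image_id = sprintf("seq%02d_img%02d", s, i),
          instance = seq_len(n_inst), minor_mm = minors)
        image_record(image_id = sprintf("seq%02d_img%02d", s, i),
                     width = W, height = H, instances = instances,
                     px_per_mm = cfg$px_per_mm, pg = pg)
      })
      sequence_record(sprintf("seq%02d", s), pg, images)
    })
  })
  attr(seqs, "truth") <- do.call(rbind, truth)
  seqs
}

#' Simulated detector model
#'
#' A stochastic stand-in for a trained recognition network: drops each
#' ground-truth instance with probability `miss_rate`, perturbs the
#' surviving polygons with Gaussian vertex jitter, adds Poisson clutter
#' false positives, and assigns confidence scores that decrease with
#' localisation error: `score = clamp(base - penalty * (1 - IoU) +
#' noise, 0, 1)`.
#'
#' @param miss_rate Probability of missing a true instance, in `[0, 1]`.
#' @param fp_per_image Poisson mean of clutter false positives per image.
#' @param jitter_sd SD (pixels) of vertex perturbation.
#' @param score_base,score_penalty,score_noise_sd Score model parameters.
#' @param clutter_size_mm Lognormal `c(meanlog, sdlog)` of clutter
#'   minor-axis sizes in mm.
#' @param seed Integer seed.
#' @return A list of class `kps_detector_model`.
#' @export
detector_model <- function(miss_rate = 0, fp_per_image = 0, jitter_sd = 0,
                           score_base = 0.95, score_penalty = 0.3,
                           score_noise_sd = 0.03,
                           clutter_size_mm = c(log(3), 0.4), seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_per_image >= 0, jitter_sd >= 0,
            score_noise_sd >= 0)
  structure(list(miss_rate = miss_rate, fp_per_image = fp_per_image,
                 jitter_sd = jitter_sd, score_base = score_base,
                 score_penalty = score_penalty,
                 score_noise_sd = score_noise_sd,
                 clutter_size_mm = clutter_size_mm, seed = seed),
            class = "kps_detector_model")
}

#' Run a simulated detector over ground-truth sequences
#'
#' @param truth List of [sequence_record()] (see [generate_dataset()]).
#' @param det A [detector_model()].
#' @return A list (parallel to `truth`) of lists of detection
#'   `kps_image` records with scored polygon instances.
#' @export
simulate_detector <- function(truth, det) {
  stopifnot(inherits(det, "kps_detector_model"))
  with_seed(det$seed, {
    lapply(truth, function(sq) {
      lapply(sq$images, function(im) {
        dets <- list()
        for (inst in im$instances) {
          if (stats::runif(1L) < det$miss_rate) next
          poly <- inst$polygon
          if (det$jitter_sd > 0)
            poly <- poly + matrix(stats::rnorm(length(poly), 0, det$jitter_sd),
                                  ncol = 2L)
          poly[, 1L] <- pmin(pmax(poly[, 1L], 0), im$width)
          poly[, 2L] <- pmin(pmax(poly[, 2L], 0), im$height)
          iou <- if (det$jitter_sd > 0) mask_iou(inst$polygon, poly) else 1
          score <- det$score_base - det$score_penalty * (1 - iou) +
            stats::rnorm(1L, 0, det$score_noise_sd)
          dets[[length(dets) + 1L]] <-
            kernel_instance(polygon = poly,
                            score = min(max(score, 0), 1))
        }
        n_fp <- stats::rpois(1L, det$fp_per_image)
        for (k in seq_len(n_fp)) {
          minor_px <- stats::rlnorm(1L, det$clutter_size_mm[1L],
                                    det$clutter_size_mm[2L]) * im$px_per_mm
          aspect <- stats::runif(1L, 1.2, 2.5)
          half <- minor_px * aspect / 2 + 1
          if (2 * half >= min(im$width, im$height)) next
          ctr <- c(stats::runif(1L, half, im$width - half),
                   stats::runif(1L, half, im$height - half))
          poly <- make_fragment_polygon(minor_px, aspect,
                                        stats::runif(1L, 0, pi), 12L, ctr)
          score <- det$score_base - det$score_penalty +
            stats::rnorm(1L, 0, det$score_noise_sd)
          dets[[length(dets) + 1L]] <-
            kernel_instance(polygon = poly, score = min(max(score, 0), 1))
        }
        image_record(image_id = im$image_id, width = im$width,
                     height = im$height, instances = dets,
                     px_per_mm = im$px_per_mm, pg = im$pg)
      })
    })
  })
}

#' The embedded 17-sequence KPS reference table
#'
#' Per-sequence Kernel Processing Scores across processor gaps of 1 to
#' 3.5 mm for eight recognition models (bounding-box R-FCN and
#' instance-segmentation MNC variants, each trained on the 2015, 2016,
#' 2017 and combined 151617 harvest datasets) together with the
#' annotation KPS, exactly as published.
#'
#' @return Data frame with 17 rows and columns `pg`, `rfcn_2015`,
#'   `mnc_2015`, `rfcn_2016`, `mnc_2016`, `rfcn_2017`, `mnc_2017`,
#'   `rfcn_151617`, `mnc_151617`, `annotation`.
#' @export
table4_kps <- function() {
  path <- system.file("extdata", "table4_kps.csv", package = "silagekps",
                      mustWork = TRUE)
  utils::read.csv(path)
}

# Model columns of the reference table, in print order.
table4_models <- function() {
  c("rfcn_2015", "mnc_2015", "rfcn_2016", "mnc_2016",
    "rfcn_2017", "mnc_2017", "rfcn_151617", "mnc_151617")
}
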