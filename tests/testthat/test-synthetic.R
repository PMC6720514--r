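test_that("generation is deterministic, bounded and shape-valid", {
  cfg <- synthetic_config(n_sequences = 3, images_per_sequence = 2,
                          instances_per_image = 6, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_equal(d1, d2)

  expect_length(generate_dataset(synthetic_config(n_sequences = 0)), 0)

  for (sq in d1) {
    expect_s3_class(sq, "kps_sequence")
    for (im in sq$images) {
      expect_equal(im$pg, sq$pg)
      for (inst in im$instances) {
        expect_false(is.null(inst$polygon))
        expect_true(all(inst$polygon[, 1] >= 0 & inst$polygon[, 1] <= im$width))
        expect_true(all(inst$polygon[, 2] >= 0 & inst$polygon[, 2] <= im$height))
      }
    }
  }

  # a different seed gives a different dataset
  d3 <- generate_dataset(synthetic_config(n_sequences = 3,
                                          images_per_sequence = 2,
                                          instances_per_image = 6, seed = 43))
  expect_false(identical(d1, d3))
})

test_that("generated minor axes are recovered exactly by the geometry module", {
  cfg <- synthetic_config(n_sequences = 2, images_per_sequence = 3,
                          instances_per_image = 10, seed = 5)
  truth <- generate_dataset(cfg)
  meta <- attr(truth, "truth")
  k <- 0
  for (sq in truth) for (im in sq$images) for (inst in im$instances) {
    k <- k + 1
    recovered <- instance_size_mm(inst, "rotated_minor",
                                  px_per_mm = im$px_per_mm)
    expect_equal(recovered, meta$minor_mm[k], tolerance = 0.02)
    # the polygonized-ellipse construction makes recovery near-exact
    expect_equal(recovered, attr(inst$polygon, "true_minor_mm"),
                 tolerance = 1e-9)
  }
  expect_gt(k, 30)
})

test_that("larger processor gaps produce lower expected KPS", {
  cfg <- synthetic_config(n_sequences = 4, pgs = c(1, 2, 3, 3.5),
                          images_per_sequence = 6, instances_per_image = 25,
                          seed = 88)
  truth <- generate_dataset(cfg)
  tab <- kps_table(truth)
  # analytic ordering of the lognormal sub-threshold mass
  p_below <- plnorm(4.75, cfg$mu_log(tab$pg), cfg$sigma_log)
  expect_true(all(diff(p_below) < 0))
  # empirical KPS follows (wide samples, monotone trend)
  expect_gt(tab$annotation[1], tab$annotation[4])
  expect_equal(order(tab$pg), seq_len(4))
})

test_that("the simulated detector honours its miss, jitter and clutter rates", {
  cfg <- synthetic_config(n_sequences = 2, images_per_sequence = 4,
                          instances_per_image = 12, seed = 19)
  truth <- generate_dataset(cfg)
  n_gt <- nrow(attr(truth, "truth"))

  # identity detector reproduces the truth exactly
  ident <- simulate_detector(truth, detector_model(seed = 1))
  polys_equal <- unlist(lapply(seq_along(truth), function(s)
    lapply(seq_along(truth[[s]]$images), function(i) {
      gt <- truth[[s]]$images[[i]]$instances
      dt <- ident[[s]][[i]]$instances
      length(gt) == length(dt) &&
        all(vapply(seq_along(gt), function(k)
          isTRUE(all.equal(unclass(gt[[k]]$polygon), unclass(dt[[k]]$polygon),
                           check.attributes = FALSE)), logical(1)))
    })))
  expect_true(all(polys_equal))

  # total miss: no detections at all
  none <- simulate_detector(truth, detector_model(miss_rate = 1, seed = 1))
  expect_equal(sum(lengths(lapply(unlist(none, recursive = FALSE),
                                  `[[`, "instances"))), 0)

  # determinism given the detector seed
  d1 <- simulate_detector(truth, detector_model(miss_rate = 0.4, jitter_sd = 2,
                                                fp_per_image = 1, seed = 9))
  d2 <- simulate_detector(truth, detector_model(miss_rate = 0.4, jitter_sd = 2,
                                                fp_per_image = 1, seed = 9))
  expect_equal(d1, d2)

  # clutter adds false positives at roughly the Poisson rate
  fp_run <- simulate_detector(truth, detector_model(fp_per_image = 3, seed = 2))
  n_det <- sum(lengths(lapply(unlist(fp_run, recursive = FALSE),
                              `[[`, "instances")))
  n_images <- sum(vapply(truth, function(s) length(s$images), numeric(1)))
  expect_gt(n_det, n_gt)  # clutter present
  expect_lt(abs((n_det - n_gt) / n_images - 3), 3 * sqrt(3 / n_images))
})

test_that("scores decrease with localisation error", {
  cfg <- synthetic_config(n_sequences = 1, images_per_sequence = 3,
                          instances_per_image = 10, seed = 31)
  truth <- generate_dataset(cfg)
  get_scores <- function(jit) {
    d <- simulate_detector(truth, detector_model(jitter_sd = jit,
                                                 score_noise_sd = 0, seed = 7))
    unlist(lapply(unlist(d, recursive = FALSE), function(im)
      vapply(im$instances, `[[`, numeric(1), "score")))
  }
  expect_gt(mean(get_scores(0)), mean(get_scores(6)))
})

test_that("the embedded reference table has the published shape and values", {
  tab <- table4_kps()
  expect_equal(nrow(tab), 17)
  expect_equal(tab$annotation[1], 93.5)
  expect_true(all(tab$pg %in% c(1, 2, 3, 3.5)))
  expect_equal(ncol(tab), 10)
  kps_cols <- setdiff(names(tab), "pg")
  expect_true(all(as.matrix(tab[kps_cols]) >= 0 &
                  as.matrix(tab[kps_cols]) <= 100))
})

test_that("the KPS calibration helper inverts the lognormal law", {
  for (p in c(0.5, 0.7, 0.9)) {
    mu <- mu_log_for_kps(p, sigma_log = 0.6)
    expect_equal(plnorm(4.75, mu, 0.6), p, tolerance = 1e-12)
  }
})
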