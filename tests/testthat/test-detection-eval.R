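test_that("matching applies the single-TP, highest-IoU, threshold rules", {
  gt <- list(box_instance(0, 0, 10, 10))

  # one detection above threshold: TP
  m <- match_detections(gt, list(box_instance(1, 0, 11, 10, score = 0.9)))
  expect_equal(nrow(m$tp_pairs), 1)
  expect_length(m$fp_det, 0)
  expect_length(m$fn_gt, 0)

  # two detections over one ground truth: higher IoU wins, other is FP
  det2 <- list(box_instance(0, 0, 10, 10, score = 0.9),   # IoU 1
               box_instance(2, 0, 12, 10, score = 0.9))   # IoU 2/3
  m2 <- match_detections(gt, det2)
  expect_equal(nrow(m2$tp_pairs), 1)
  expect_equal(m2$tp_pairs$det, 1)
  expect_equal(m2$fp_det, 2)

  # below threshold: FP + FN
  m3 <- match_detections(gt, list(box_instance(7, 0, 17, 10, score = 0.9)))
  expect_equal(nrow(m3$tp_pairs), 0)
  expect_equal(m3$fp_det, 1)
  expect_equal(m3$fn_gt, 1)

  # counts always partition: tp + fn = |GT|, tp + fp = |det|
  for (m in list(m, m2, m3)) {
    expect_equal(nrow(m$tp_pairs) + length(m$fn_gt), 1)
  }

  # raising the IoU threshold never adds true positives
  m_lo <- match_detections(gt, det2, iou_threshold = 0.5)
  m_hi <- match_detections(gt, det2, iou_threshold = 0.9)
  expect_lte(nrow(m_hi$tp_pairs), nrow(m_lo$tp_pairs))

  # mask mode requires polygons
  boxonly <- kernel_instance(box = c(0, 0, 5, 5), score = 0.5)
  expect_error(match_detections(gt, list(boxonly), mode = "mask"), "polygon")
})

test_that("matching agrees with exhaustive assignment search on small cases", {
  set.seed(2024)
  for (case in 1:200) {
    ng <- sample(0:4, 1)
    nd <- sample(0:4, 1)
    gts <- lapply(seq_len(ng), function(i) {
      x <- runif(1, 0, 60); y <- runif(1, 0, 60)
      box_instance(x, y, x + runif(1, 8, 20), y + runif(1, 8, 20))
    })
    dets <- lapply(seq_len(nd), function(j) {
      if (ng > 0 && runif(1) < 0.8) {
        g <- gts[[sample(ng, 1)]]$box
        jit <- runif(4, -4, 4)
        box_instance(g[1] + jit[1], g[2] + jit[2],
                     max(g[1] + jit[1] + 1, g[3] + jit[3]),
                     max(g[2] + jit[2] + 1, g[4] + jit[4]),
                     score = runif(1))
      } else {
        x <- runif(1, 0, 60); y <- runif(1, 0, 60)
        box_instance(x, y, x + runif(1, 8, 20), y + runif(1, 8, 20),
                     score = runif(1))
      }
    })
    m <- match_detections(gts, dets, iou_threshold = 0.5)
    iou <- matrix(0, ng, nd)
    if (ng > 0 && nd > 0)
      for (i in 1:ng) for (j in 1:nd)
        iou[i, j] <- box_iou(gts[[i]]$box, dets[[j]]$box)
    oracle <- exhaustive_match(iou, 0.5)
    expect_equal(nrow(m$tp_pairs), oracle$tp,
                 info = sprintf("case %d: greedy TP != exhaustive TP", case))
    expect_equal(length(m$fp_det), nd - oracle$tp)
    expect_equal(length(m$fn_gt), ng - oracle$tp)
  }
})

test_that("precision, recall and F1 follow their defining ratios", {
  fake_match <- function(tp, fp, fn) {
    structure(list(tp_pairs = data.frame(gt = seq_len(tp), det = seq_len(tp),
                                         iou = rep(1, tp)),
                   fp_det = seq_len(fp), fn_gt = seq_len(fn),
                   iou_threshold = 0.5),
              class = "kps_match")
  }
  expect_equal(precision_recall_f1(fake_match(5, 0, 0)),
               c(precision = 100, recall = 100, f1 = 100))
  r <- precision_recall_f1(fake_match(3, 1, 2))
  expect_equal(unname(r["precision"]), 75)
  expect_equal(unname(r["recall"]), 60)
  expect_equal(unname(r["f1"]), 100 * 6 / 9)
  # degenerate: no detections at all
  r0 <- precision_recall_f1(fake_match(0, 0, 3))
  expect_equal(unname(r0["precision"]), 0)
  expect_equal(unname(r0["recall"]), 0)
  expect_equal(unname(r0["f1"]), 0)
})

test_that("11-point AP reproduces hand-enumerated ranked lists", {
  gt <- list(image_record("i", 200, 200, instances = list(
    box_instance(0, 0, 10, 10),
    box_instance(50, 50, 60, 60),
    box_instance(100, 100, 110, 110))))

  # perfect detector
  det_perfect <- list(image_record("i", 200, 200, instances = list(
    box_instance(0, 0, 10, 10, score = 0.9),
    box_instance(50, 50, 60, 60, score = 0.8),
    box_instance(100, 100, 110, 110, score = 0.7))))
  expect_equal(average_precision(gt, det_perfect), 100)

  # nothing reaches IoU 0.5
  det_bad <- list(image_record("i", 200, 200, instances = list(
    box_instance(150, 0, 160, 10, score = 0.9))))
  expect_equal(average_precision(gt, det_bad), 0)

  # ranked (TP, FP, TP) over 3 ground truths: AP = 6/11
  det_mixed <- list(image_record("i", 200, 200, instances = list(
    box_instance(0, 0, 10, 10, score = 0.9),       # TP
    box_instance(150, 0, 160, 10, score = 0.8),    # FP
    box_instance(50, 50, 60, 60, score = 0.7))))   # TP
  expect_equal(average_precision(gt, det_mixed), 100 * 6 / 11)

  # AP is invariant to strictly monotone score transforms
  det_sq <- det_mixed
  det_sq[[1]]$instances <- lapply(det_sq[[1]]$instances, function(d) {
    d$score <- d$score^3; d
  })
  expect_equal(average_precision(gt, det_sq), average_precision(gt, det_mixed))

  # unscored detections are rejected
  det_nos <- list(image_record("i", 200, 200,
                               instances = list(box_instance(0, 0, 10, 10))))
  expect_error(average_precision(gt, det_nos), "unscored")
})

test_that("dataset evaluation aggregates counts and modes consistently", {
  gt <- list(image_record("i", 200, 200, instances = list(
    box_instance(0, 0, 20, 20), box_instance(60, 60, 90, 90))))
  det <- list(image_record("i", 200, 200, instances = list(
    box_instance(0, 0, 20, 20, score = 0.9),
    box_instance(60, 60, 90, 90, score = 0.8))))
  rep_box <- evaluate_dataset(gt, det, mode = "box")
  expect_equal(rep_box$precision, 100)
  expect_equal(rep_box$recall, 100)
  expect_equal(rep_box$ap, 100)
  # boxes are their own masks: identical rectangles give identical reports
  rep_mask <- evaluate_dataset(gt, det, mode = "mask")
  expect_equal(rep_mask[c("precision", "recall", "f1", "ap", "tp", "fp", "fn")],
               rep_box[c("precision", "recall", "f1", "ap", "tp", "fp", "fn")])

  # empty annotation set: recall undefined (NA), AP 0
  rep_empty <- evaluate_dataset(list(image_record("i", 200, 200)), det,
                                mode = "box")
  expect_true(is.na(rep_empty$recall))
  expect_equal(rep_empty$ap, 0)

  # score threshold removes low-confidence detections from the counts
  det_lo <- list(image_record("i", 200, 200, instances = list(
    box_instance(0, 0, 20, 20, score = 0.9),
    box_instance(120, 120, 150, 150, score = 0.1))))
  rep_thr <- evaluate_dataset(gt, det_lo, mode = "box", score_threshold = 0.5)
  expect_equal(rep_thr$fp, 0)
  rep_all <- evaluate_dataset(gt, det_lo, mode = "box")
  expect_equal(rep_all$fp, 1)
})

test_that("a 30% miss-rate detector recovers recall near 70%", {
  cfg <- synthetic_config(n_sequences = 5, images_per_sequence = 8,
                          instances_per_image = 25, seed = 314)
  truth <- generate_dataset(cfg)
  n_gt <- nrow(attr(truth, "truth"))
  expect_gte(n_gt, 1000 * 0.8)  # enough instances for a tight binomial SE
  det <- detector_model(miss_rate = 0.3, fp_per_image = 0, jitter_sd = 0,
                        seed = 2718)
  dets <- simulate_detector(truth, det)
  rep <- evaluate_dataset(unlist(lapply(truth, `[[`, "images"), recursive = FALSE),
                          unlist(dets, recursive = FALSE), mode = "box")
  se <- 100 * sqrt(0.3 * 0.7 / n_gt)
  expect_lt(abs(rep$recall - 70), 3 * se)
  expect_equal(rep$precision, 100)
})
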