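box_df <- function(image_id, class_id, x1, y1, x2, y2, score = NULL) {
  df <- data.frame(image_id = image_id, class_id = class_id,
                   x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  if (!is.null(score)) df$score <- score
  df
}

test_that("iou covers identity, disjoint and partial overlap", {
  a <- c(0, 0, 1, 1)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(a, c(0.5, 0, 1.5, 1)), 1 / 3)  # overlap 0.5, union 1.5
})

test_that("greedy matching enforces one match per ground truth", {
  gts <- box_df(1, 1, x1 = seq(0, 80, by = 20), y1 = 0,
                x2 = seq(10, 90, by = 20), y2 = 10)
  perfect <- gts
  perfect$score <- seq(0.9, 0.5, by = -0.1)
  m <- match_detections(perfect, gts)
  expect_equal(m, list(tp = 5L, fp = 0L, fn = 0L))

  dup <- box_df(1, 1, x1 = c(0, 1), y1 = c(0, 1), x2 = c(10, 11), y2 = c(10, 11),
                score = c(0.9, 0.8))
  one_gt <- box_df(1, 1, 0, 0, 10, 10)
  m2 <- match_detections(dup, one_gt)
  expect_equal(m2$tp, 1L)
  expect_equal(m2$fp, 1L)
  expect_equal(m2$fn, 0L)
})

test_that("matching counts agree with an independent brute-force matcher", {
  for (seed in 1:6) {
    set.seed(seed * 13)
    n_gt <- 10
    gx <- runif(n_gt, 0, 200); gy <- runif(n_gt, 0, 200)
    gts <- box_df(1, sample(1:2, n_gt, TRUE), gx, gy, gx + 20, gy + 20)
    n_p <- 12
    px <- c(gx[1:8] + runif(8, -6, 6), runif(4, 0, 200))
    py <- c(gy[1:8] + runif(8, -6, 6), runif(4, 0, 200))
    preds <- box_df(1, c(gts$class_id[1:8], sample(1:2, 4, TRUE)),
                    px, py, px + 20, py + 20, score = runif(n_p))
    m <- match_detections(preds, gts, iou_thr = 0.5)
    o <- brute_match(preds, gts, iou_thr = 0.5)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fp, o$fp)
    expect_equal(m$fn, o$fn)
  }
})

test_that("precision and recall follow the count formulas with 0/0 -> 0", {
  expect_equal(precision_recall(7, 3, 0)$precision, 0.7)
  expect_equal(precision_recall(7, 0, 3)$recall, 0.7)
  expect_equal(precision_recall(0, 0, 5), list(precision = 0, recall = 0))
  expect_error(precision_recall(-1, 0, 0), "non-negative")
})

test_that("average precision integrates the interpolated PR curve", {
  gts <- box_df(1, 1, x1 = c(0, 20, 40), y1 = 0, x2 = c(10, 30, 50), y2 = 10)
  perfect <- gts
  perfect$score <- c(0.9, 0.8, 0.7)
  expect_equal(average_precision(perfect, gts), 1)

  # ranked TP, FP, TP, FP, TP, FP(duplicate): hand-integrated AP = 34/45
  preds <- box_df(
    1, 1,
    x1 = c(0, 100, 20, 120, 40, 1),
    y1 = c(0, 100, 0, 120, 0, 1),
    x2 = c(10, 110, 30, 130, 50, 11),
    y2 = c(10, 110, 10, 130, 10, 11),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  expect_equal(average_precision(preds, gts), 34 / 45, tolerance = 1e-12)

  # single-class mAP equals AP
  dm <- detection_metrics(perfect, gts)
  expect_equal(dm$map, unname(dm$ap_per_class))
  expect_equal(dm$precision, 1)
  expect_equal(dm$recall, 1)
})

test_that("removing a false positive never decreases AP; mAP <= max AP", {
  for (seed in 1:5) {
    set.seed(seed)
    gx <- runif(6, 0, 150)
    gts <- box_df(1, rep(1:2, 3), gx, gx, gx + 15, gx + 15)
    px <- c(gx + runif(6, -4, 4), runif(3, 200, 300))
    preds <- box_df(1, c(gts$class_id, rep(1, 3)), px, px, px + 15, px + 15,
                    score = runif(9))
    fp_rows <- 7:9
    ap_all <- average_precision(preds[preds$class_id == 1, ], gts[gts$class_id == 1, ])
    ap_cut <- average_precision(preds[-fp_rows, ][preds$class_id[-fp_rows] == 1, ],
                                gts[gts$class_id == 1, ])
    expect_gte(ap_cut + 1e-12, ap_all)

    dm <- detection_metrics(preds, gts)
    expect_lte(dm$map, max(dm$ap_per_class) + 1e-12)
  }
})

test_that("classes without ground truths are excluded with a warning", {
  gts <- box_df(1, 1, 0, 0, 10, 10)
  preds <- box_df(1, c(1, 9), c(0, 50), c(0, 50), c(10, 60), c(10, 60),
                  score = c(0.9, 0.8))
  expect_warning(dm <- detection_metrics(preds, gts), "no ground truths")
  expect_equal(names(dm$ap_per_class), "1")
})

test_that("AP is invariant to prediction row order", {
  gts <- box_df(1, 1, x1 = c(0, 30), y1 = 0, x2 = c(10, 40), y2 = 10)
  preds <- box_df(1, 1, x1 = c(0, 30, 70), y1 = c(0, 0, 0),
                  x2 = c(10, 40, 80), y2 = c(10, 10, 10),
                  score = c(0.9, 0.4, 0.6))
  shuffled <- preds[c(3, 1, 2), ]
  expect_equal(average_precision(preds, gts), average_precision(shuffled, gts))
})
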