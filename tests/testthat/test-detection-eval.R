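# Detection metrics: matching, precision/recall, COCO-style AP/AR, and the
# counting error measures.

tb <- function(x1, y1, x2, y2, conf = NULL, image_id = NULL) {
  out <- tibble::tibble(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  if (!is.null(conf)) out$conf <- conf
  if (!is.null(image_id)) out$image_id <- image_id
  out
}

test_that("precision/recall arithmetic and conventions", {
  # 10 gts; 8 matched detections + 2 false positives -> Pr = Re = 0.8
  gts <- tb(seq(0, 900, by = 100), 0, seq(50, 950, by = 100), 50)
  hit <- tb(gts$x1[1:8], 0, gts$x2[1:8], 50, conf = seq(0.9, 0.2, length.out = 8))
  fp <- tb(c(2000, 3000), 0, c(2050, 3050), 50, conf = c(0.5, 0.4))
  pr <- precision_recall(rbind(hit, fp), gts, 0.5)
  expect_equal(pr$tp, 8); expect_equal(pr$fp, 2); expect_equal(pr$fn, 2)
  expect_equal(pr$precision, 0.8); expect_equal(pr$recall, 0.8)
  # perfect matching
  pp <- precision_recall(cbind(gts, conf = 0.9), gts, 0.5)
  expect_equal(c(pp$precision, pp$recall), c(1, 1))
  # no detections at all
  p0 <- precision_recall(tb(numeric(), numeric(), numeric(), numeric(),
                            conf = numeric()), gts, 0.5)
  expect_equal(c(p0$precision, p0$recall), c(0, 0))
})

test_that("matching never assigns one ground truth to two detections", {
  set.seed(601)
  for (i in 1:25) {
    n_g <- sample(1:8, 1); n_d <- sample(1:12, 1)
    gx <- runif(n_g, 0, 200); gy <- runif(n_g, 0, 200)
    gts <- tb(gx, gy, gx + runif(n_g, 20, 60), gy + runif(n_g, 20, 60))
    dx <- runif(n_d, 0, 200); dy <- runif(n_d, 0, 200)
    dets <- tb(dx, dy, dx + runif(n_d, 20, 60), dy + runif(n_d, 20, 60),
               conf = runif(n_d))
    m <- match_detections(dets, gts, 0.3)
    if (nrow(m$pairs)) expect_equal(anyDuplicated(m$pairs[, "gt"]), 0L)
    expect_equal(m$tp + m$fn, n_g)
    expect_equal(m$tp + m$fp, n_d)
  }
})

test_that("average precision: degenerate and hand-built curves", {
  g <- tb(0, 0, 50, 50)
  d_perfect <- tb(0, 0, 50, 50, conf = 0.9)
  expect_equal(average_precision(d_perfect, g, iou_thrs = 0.5), 1)
  # FP at conf .9 then TP at conf .8 over one gt -> 101-point AP@50 = 0.5
  d2 <- tb(c(200, 0), c(200, 0), c(250, 50), c(250, 50), conf = c(0.9, 0.8))
  expect_equal(average_precision(d2, g, iou_thrs = 0.5), 0.5)
  # no detections -> AP = 0
  expect_equal(average_precision(d_perfect[0, ], g, iou_thrs = 0.5), 0)
})

test_that("AP is bounded and AP@50 dominates the averaged AP", {
  set.seed(602)
  for (i in 1:10) {
    n_g <- sample(2:6, 1); n_d <- sample(2:10, 1)
    gx <- runif(n_g, 0, 150); gy <- runif(n_g, 0, 150)
    gts <- tb(gx, gy, gx + 40, gy + 40, image_id = 1L)
    jx <- runif(n_d, -20, 170); jy <- runif(n_d, -20, 170)
    dets <- tb(jx, jy, jx + 40, jy + 40, conf = runif(n_d), image_id = 1L)
    ap <- average_precision(dets, gts)
    ap50 <- average_precision(dets, gts, iou_thrs = 0.5)
    expect_gte(ap, 0); expect_lte(ap, 1)
    expect_gte(ap50 + 1e-12, ap)
  }
})

test_that("scale-restricted AP isolates the targeted size band", {
  # one small (20 px) and one large (120 px) gt; detections hit only the small
  gts <- tb(c(10, 200), c(10, 200), c(30, 320), c(30, 320), image_id = 1L)
  dets <- tb(10, 10, 30, 30, conf = 0.9, image_id = 1L)
  expect_equal(average_precision(dets, gts, iou_thrs = 0.5,
                                 scale_filter = "small"), 1)
  expect_equal(average_precision(dets, gts, iou_thrs = 0.5,
                                 scale_filter = "large"), 0)
  # the small-only evaluation does not punish the unmatched large gt's absence
  expect_equal(average_recall(dets, gts, iou_thrs = 0.5,
                              scale_filter = "small"), 1)
})

test_that("eval_detections returns the full metric set with tidy methods", {
  gts <- tb(c(0, 100), c(0, 100), c(40, 160), c(40, 160), image_id = 1L)
  dets <- tb(c(0, 100), c(0, 100), c(40, 160), c(40, 160),
             conf = c(0.9, 0.8), image_id = 1L)
  ev <- eval_detections(dets, gts)
  expect_s3_class(ev, "spike_eval")
  expect_equal(ev$ap50, 1)
  expect_equal(ev$ar, 1)
  td <- tidy(ev)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_equal(nrow(glance(ev)), 1L)
})

test_that("counting metrics: worked example and conventions", {
  cm <- count_metrics(c(10, 20, 30), c(12, 19, 33))
  expect_equal(cm$mae, 2)
  expect_equal(cm$rmse, sqrt(14 / 3), tolerance = 1e-9)
  expect_equal(cm$r2, 1 - 14 / 200)
  # exact predictions
  cm0 <- count_metrics(c(3, 7, 9), c(3, 7, 9))
  expect_equal(c(cm0$mae, cm0$rmse, cm0$r2), c(0, 0, 1))
  # predicting the mean gives R2 = 0
  cmm <- count_metrics(c(10, 20, 30), rep(20, 3))
  expect_equal(cmm$r2, 0)
  # negative R2 for a predictor worse than the mean
  expect_lt(count_metrics(c(10, 20, 30), c(30, 10, 35))$r2, 0)
  # zero variance in y -> undefined
  expect_true(is.na(count_metrics(c(5, 5, 5), c(4, 5, 6))$r2))
})

test_that("MAE never exceeds RMSE over 1000 random series", {
  set.seed(603)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- rpois(n, 20)
    yh <- pmax(0, y + rnorm(n, sd = sample(1:10, 1)))
    cm <- count_metrics(y, yh)
    if (cm$mae > cm$rmse + 1e-12) fail("MAE exceeded RMSE")
  }
  succeed()
})

test_that("detection-to-count bridge is monotone in the threshold", {
  set.seed(604)
  dets <- tb(runif(30), runif(30), runif(30) + 2, runif(30) + 2,
             conf = runif(30))
  counts <- vapply(seq(0, 1, by = 0.05), function(th)
    detections_to_count(dets, th), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(detections_to_count(dets[0, ], 0.5), 0L)
  # 5 detections, 3 at or above the threshold
  d5 <- tb(rep(1, 5), rep(1, 5), rep(2, 5), rep(2, 5),
           conf = c(0.9, 0.5, 0.3, 0.2, 0.1))
  expect_equal(detections_to_count(d5, 0.25), 3L)
})
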