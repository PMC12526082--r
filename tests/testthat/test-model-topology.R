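# Assembly of the detector variants: pyramid strides, flag composition, the
# bidirectional-neck wiring, and the decode path contracts.

small_cfg <- function(...) {
  variant_config(..., width_scale = 0.25, input_size = 64L)
}

test_that("backbone pyramid sits at strides 4/8/16/32 (P3 80, P4 40, P5 20 at 640)", {
  m <- build_model(variant_config())
  probe <- sd_shape(3, 640, 640)
  feats <- backbone_features(m, probe)
  expect_equal(feats$P3$dims[["H"]], 80L)
  expect_equal(feats$P4$dims[["H"]], 40L)
  expect_equal(feats$P5$dims[["H"]], 20L)
  expect_equal(feats$P2$dims[["H"]], 160L)
})

test_that("variant flags compose independently and build deterministic graphs", {
  combos <- expand.grid(f = c(FALSE, TRUE), b = c(FALSE, TRUE),
                        a = c(FALSE, TRUE), g = c(FALSE, TRUE))
  counts <- apply(combos, 1, function(r) {
    m <- build_model(small_cfg(r[["f"]], r[["b"]], r[["a"]], r[["g"]]))
    count_parameters(m)
  })
  expect_true(all(counts > 0))
  # two builds of the same config have identical parameter counts
  for (i in c(1L, 8L, 16L)) {
    r <- combos[i, ]
    m1 <- build_model(small_cfg(r$f, r$b, r$a, r$g))
    m2 <- build_model(small_cfg(r$f, r$b, r$a, r$g))
    expect_identical(count_parameters(m1), count_parameters(m2))
    expect_identical(estimate_flops(m1, 64), estimate_flops(m2, 64))
  }
})

test_that("the feature-enhancement backbone strictly reduces parameters", {
  base <- count_parameters(build_model(variant_config()))
  fem <- count_parameters(build_model(variant_config(use_femanet = TRUE)))
  expect_lt(fem, base)
  # and the reduction is in the backbone itself
  bb_base <- build_backbone(variant_config())
  bb_fem <- build_backbone(variant_config(use_femanet = TRUE))
  expect_lt(count_parameters(bb_fem), count_parameters(bb_base))
  f <- backbone_features(bb_fem, sd_shape(3, 640, 640))
  expect_equal(vapply(f, function(x) x$dims[["H"]], integer(1)),
               c(P2 = 160L, P3 = 80L, P4 = 40L, P5 = 20L))
})

test_that("bidirectional neck emits one stride-8 and two stride-16 levels, no stride 32", {
  m <- build_model(variant_config(use_biafa_fpn = TRUE))
  expect_equal(m$strides, c(8L, 16L, 16L))
  preds <- forward_model(m, sd_shape(3, 640, 640))
  expect_length(preds, 3L)
  # resolution contract: P3-scale output matches P3in, both P4 outputs match P4in
  expect_equal(preds[[1]]$box$dims[["H"]], 80L)
  expect_equal(preds[[2]]$box$dims[["H"]], 40L)
  expect_equal(preds[[3]]$box$dims[["H"]], 40L)
})

test_that("the first stride-16 output node fuses exactly four sources", {
  m <- build_model(variant_config(use_biafa_fpn = TRUE))
  # model$levels[2] is the C3k2 of the first P4-scale output; its input is a
  # concat node whose fan-in is the wiring under audit
  fuse_node <- m$layers[[m$levels[2]]]
  concat_node <- m$layers[[fuse_node$from]]
  expect_s3_class(concat_node$m, "sd_concat")
  expect_length(concat_node$from, 4L)
  # and the P3-scale output fuses two sources, the second P4 output two
  expect_length(m$layers[[m$layers[[m$levels[1]]]$from]]$from, 2L)
  expect_length(m$layers[[m$layers[[m$levels[3]]]$from]]$from, 2L)
  # missing P2 ingestion would break the wiring: the P3 top-down node sees 3
  tags <- vapply(m$layers, function(l) l$tag %||% "", character(1))
  p3td_concat <- Find(function(l) inherits(l$m, "sd_concat") &&
                        length(l$from) == 3L && l$stride == 8L, m$layers)
  expect_false(is.null(p3td_concat))
})

test_that("decode path: duplicate suppression, thresholding, box clipping", {
  b <- tibble::tibble(x1 = c(10, 10.5, 50), y1 = c(10, 10.2, 50),
                      x2 = c(30, 30.4, 70), y2 = c(30, 30.1, 70),
                      conf = c(0.9, 0.8, 0.7))
  kept <- nms_boxes(b, 0.55)
  expect_equal(nrow(kept), 2L)        # the near-duplicate is suppressed
  expect_equal(kept$conf[1], 0.9)
  set.seed(301)
  m <- build_model(small_cfg(TRUE, TRUE, TRUE, TRUE))
  img <- array(runif(96 * 80 * 3, 0, 255), c(96, 80, 3))
  dets <- forward_detect(m, img, conf_thr = 0, nms_iou = 0.55)
  if (nrow(dets)) {
    expect_true(all(dets$x1 >= 0 & dets$x2 <= 80 & dets$y1 >= 0 &
                      dets$y2 <= 96))
    expect_true(all(dets$x1 < dets$x2 & dets$y1 < dets$y2))
  }
  # all outputs below threshold -> empty tibble, not an error
  none <- forward_detect(m, img, conf_thr = 1)
  expect_equal(nrow(none), 0L)
})

test_that("head strides are 8/16/32 with the baseline neck", {
  m <- build_model(variant_config())
  expect_equal(m$strides, c(8L, 16L, 32L))
  preds <- forward_model(m, sd_shape(3, 320, 320))
  expect_length(preds, 3L)
  expect_equal(vapply(preds, function(p) p$box$dims[["H"]], integer(1)),
               c(40L, 20L, 10L))
  expect_equal(dim(preds <- NULL), NULL)
})
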