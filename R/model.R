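# Network assembly: the nano-scale baseline detector graph and the ablation
# ladder that swaps in the four bespoke modules, plus the inference decode
# path (DFL -> boxes -> confidence filter -> NMS).

#' Model variant configuration
#'
#' Flags select which bespoke modules replace baseline components; all flags
#' off reproduces the baseline graph, all on is the full lightweight model.
#' Flags compose independently.
#'
#' @param use_femanet replace backbone feature blocks with the
#'   mixed-aggregation block (and its slimmer deep-stage widths)
#' @param use_biafa_fpn replace the PAN neck with the bidirectional asymmetric
#'   feature pyramid (outputs: one stride-8 and two stride-16 levels)
#' @param use_adown replace backbone stage-transition convs with adaptive
#'   downsampling (the stem is untouched)
#' @param use_gscdhead replace the decoupled head with the group-normalized
#'   shared-convolution head
#' @param width_scale,depth_scale global scaling of channel widths / block
#'   repeats (1 = nano)
#' @param num_classes object classes (1 for wheat spikes)
#' @param input_size square input side in pixels
#' @param reg_max DFL bins per box side
#' @param arch advanced architecture knobs, see [arch_defaults()]
#' @return a `variant_config`
#' @export
variant_config <- function(use_femanet = FALSE, use_biafa_fpn = FALSE,
                           use_adown = FALSE, use_gscdhead = FALSE,
                           width_scale = 1, depth_scale = 1,
                           num_classes = 1L, input_size = 640L,
                           reg_max = 16L, arch = arch_defaults()) {
  stopifnot(width_scale > 0, depth_scale > 0, num_classes >= 1L, input_size >= 32L)
  structure(list(use_femanet = use_femanet, use_biafa_fpn = use_biafa_fpn,
                 use_adown = use_adown, use_gscdhead = use_gscdhead,
                 width_scale = width_scale, depth_scale = depth_scale,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 reg_max = as.integer(reg_max), arch = arch),
            class = "variant_config")
}

#' Architecture knobs left open by the printed model description
#'
#' Channel widths and inner ratios that the source architecture never
#' tabulates; the defaults were calibrated once against the printed
#' parameter/GFLOP ladder and are not meant to be user-tuned.
#'
#' @param widths named per-node channel widths at nano scale
#' @param fem_widths width overrides applied when the mixed-aggregation
#'   backbone is selected (its deep stages are slimmer)
#' @param biafa_widths fusion-node output widths of the bidirectional neck
#' @param fem_e hidden ratio c/out_channels of the mixed-aggregation block
#' @param fem_x2_ratio spatial-path output width in units of c (2 keeps 2c)
#' @param partial_ratio,expansion partial-conv block hyper-parameters
#' @param hidc shared-head width (NULL = smallest head input level)
#' @param adown_neck also use adaptive downsampling inside the neck
#' @export
arch_defaults <- function(widths = c(stem = 16, t1 = 32, s2 = 64, t3 = 64,
                                     s4 = 128, t5 = 128, s6 = 128, t7 = 256,
                                     s8 = 256, n13 = 128, n16 = 64, n19 = 128,
                                     n22 = 256),
                          fem_widths = c(t5 = 64, s6 = 64, t7 = 64, s8 = 96,
                                         n16 = 48, n19 = 152, n22 = 240),
                          biafa_widths = c(p5td = 72, p4td = 72, p3td = 64,
                                           p3out = 64, p4out = 72, p4outp = 72),
                          fem_e = c(0.5, 0.5, 0.5, 0.5), fem_x2_ratio = 1L,
                          partial_ratio = 0.25, expansion = 2L,
                          hidc = 64L, adown_neck = TRUE,
                          biafa_e = 0.5, biafa_c3k = FALSE, rconv_k = 3L,
                          rconv_frac = 0.5) {
  list(widths = widths, fem_widths = fem_widths, biafa_widths = biafa_widths,
       fem_e = fem_e, fem_x2_ratio = fem_x2_ratio,
       partial_ratio = partial_ratio, expansion = expansion,
       hidc = hidc, adown_neck = adown_neck, biafa_e = biafa_e, biafa_c3k = biafa_c3k,
       rconv_k = rconv_k, rconv_frac = rconv_frac)
}

scale_w <- function(x, s) {
  if (s == 1) return(as.integer(x))
  as.integer(pmax(4L, ceiling(x * s / 4) * 4L))
}

# Paramless graph nodes -------------------------------------------------------

nn_upsample <- function() new_module("upsample", c_out = NA_integer_)
#' @export
fwd.sd_upsample <- function(m, x, ...) op_upsample2(x)

nn_concat <- function(c_out) new_module("concat", c_out = c_out)
#' @export
fwd.sd_concat <- function(m, x, ...) op_concat(x)

# Graph builder ---------------------------------------------------------------

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$layers <- list()
  g$ch <- integer(0)
  g
}

g_add <- function(g, from, mod, stride = NA_integer_, tag = NULL) {
  # force both promises first: evaluating them may itself append nodes
  from <- as.integer(from)
  force(mod)
  i <- length(g$layers) + 1L
  g$layers[[i]] <- list(from = as.integer(from), m = mod, stride = stride,
                        tag = tag)
  co <- mod$c_out
  if (is.na(co) && inherits(mod, "sd_upsample")) {
    src <- if (from[1] == -1L) i - 1L else from[1]
    co <- g$ch[src]
  }
  g$ch[i] <- co
  i
}

#' Assemble a detector variant
#'
#' Builds the computation graph for the selected module combination. The
#' returned model exposes `$layers` (topologically ordered graph), the head
#' node, and the feature levels feeding it.
#'
#' @param cfg a [variant_config()]
#' @return an `sd_model`
#' @export
build_model <- function(cfg = variant_config()) {
  a <- cfg$arch
  W <- a$widths
  if (cfg$use_femanet && length(a$fem_widths)) W[names(a$fem_widths)] <- a$fem_widths
  w <- function(nm) scale_w(W[[nm]], cfg$width_scale)
  nrep <- function(n) max(1L, as.integer(round(n * cfg$depth_scale)))
  g <- new_graph()

  # stage feature block; `e` is the stage's hidden-width ratio (the first two
  # stages of the nano baseline use 0.25, deeper ones 0.5 -- the
  # mixed-aggregation replacement inherits the same per-stage ratio)
  stage_block <- function(stage, c_in, c_out, n, c3k, e = 0.5) {
    if (cfg$use_femanet) {
      nn_mixed_aggregation(c_in, block_config(
        out_channels = c_out, n_repeats = n,
        partial_ratio = a$partial_ratio, expansion = a$expansion,
        hidden_ratio = rep_len(a$fem_e, 4L)[stage], x2_ratio = a$fem_x2_ratio))
    } else nn_c3k2(c_in, c_out, n = n, c3k = c3k, e = e)
  }
  down <- function(c_in, c_out, in_neck = FALSE) {
    if (cfg$use_adown && (!in_neck || a$adown_neck)) nn_adown(c_in, c_out)
    else nn_conv(c_in, c_out, 3L, s = 2L)
  }

  # --- backbone ---
  stem <- g_add(g, -1L, nn_conv(3L, w("stem"), 3L, s = 2L), stride = 2L)
  t1 <- g_add(g, -1L, down(w("stem"), w("t1")), stride = 4L)
  s2 <- g_add(g, -1L, stage_block(1L, w("t1"), w("s2"), nrep(1L), FALSE, e = 0.25),
              stride = 4L, tag = "P2")
  t3 <- g_add(g, -1L, down(w("s2"), w("t3")), stride = 8L)
  s4 <- g_add(g, -1L, stage_block(2L, w("t3"), w("s4"), nrep(1L), FALSE, e = 0.25),
              stride = 8L, tag = "P3")
  t5 <- g_add(g, -1L, down(w("s4"), w("t5")), stride = 16L)
  s6 <- g_add(g, -1L, stage_block(3L, w("t5"), w("s6"), nrep(1L), TRUE),
              stride = 16L, tag = "P4")
  t7 <- g_add(g, -1L, down(w("s6"), w("t7")), stride = 32L)
  s8 <- g_add(g, -1L, stage_block(4L, w("t7"), w("s8"), nrep(1L), TRUE), stride = 32L)
  sppf <- g_add(g, -1L, nn_sppf(w("s8"), w("s8")), stride = 32L)
  psa <- g_add(g, -1L, nn_c2psa(w("s8"), n = nrep(1L)), stride = 32L, tag = "P5")

  p2 <- s2; p3 <- s4; p4 <- s6; p5 <- psa

  if (!cfg$use_biafa_fpn) {
    # --- baseline PAN neck ---
    u1 <- g_add(g, p5, nn_upsample(), stride = 16L)
    c1 <- g_add(g, c(u1, p4), nn_concat(g$ch[u1] + g$ch[p4]), stride = 16L)
    n13 <- g_add(g, -1L, nn_c3k2(g$ch[c1], w("n13"), n = nrep(1L), c3k = FALSE),
                 stride = 16L)
    u2 <- g_add(g, -1L, nn_upsample(), stride = 8L)
    c2 <- g_add(g, c(u2, p3), nn_concat(g$ch[u2] + g$ch[p3]), stride = 8L)
    n16 <- g_add(g, -1L, nn_c3k2(g$ch[c2], w("n16"), n = nrep(1L), c3k = FALSE),
                 stride = 8L)
    d1 <- g_add(g, -1L, down(w("n16"), w("n16"), in_neck = TRUE), stride = 16L)
    c3 <- g_add(g, c(d1, n13), nn_concat(g$ch[d1] + g$ch[n13]), stride = 16L)
    n19 <- g_add(g, -1L, nn_c3k2(g$ch[c3], w("n19"), n = nrep(1L), c3k = FALSE),
                 stride = 16L)
    d2 <- g_add(g, -1L, down(w("n19"), w("n19"), in_neck = TRUE), stride = 32L)
    c4 <- g_add(g, c(d2, p5), nn_concat(g$ch[d2] + g$ch[p5]), stride = 32L)
    n22 <- g_add(g, -1L, nn_c3k2(g$ch[c4], w("n22"), n = nrep(1L), c3k = TRUE),
                 stride = 32L)
    levels <- c(n16, n19, n22)
    strides <- c(8L, 16L, 32L)
  } else {
    # --- bidirectional asymmetric feature pyramid ---
    bw <- vapply(a$biafa_widths, function(x) scale_w(x, cfg$width_scale), integer(1))
    names(bw) <- names(a$biafa_widths)
    fuse <- function(from, c_out, stride) {
      ci <- g_add(g, from, nn_concat(sum(g$ch[from])), stride = stride)
      g_add(g, ci, nn_c3k2(g$ch[ci], c_out, n = nrep(1L), c3k = a$biafa_c3k,
                           e = a$biafa_e),
            stride = stride)
    }
    rdown <- function(src, stride) {
      co <- scale_w(max(8, round(g$ch[src] * a$rconv_frac / 8) * 8), 1)
      if (cfg$use_adown && a$adown_neck) {
        g_add(g, src, nn_adown(g$ch[src], co), stride = stride)
      } else {
        g_add(g, src, nn_conv(g$ch[src], co, a$rconv_k, s = 2L,
                              p = autopad(a$rconv_k)), stride = stride)
      }
    }
    rup <- function(src, stride) g_add(g, src, nn_upsample(), stride = stride)

    # top-down intermediates
    p5td <- fuse(c(p5, rdown(p4, 32L)), bw[["p5td"]], 32L)
    p4td <- fuse(c(p4, rdown(p3, 16L), rup(p5td, 16L)), bw[["p4td"]], 16L)
    p3td <- fuse(c(p3, rdown(p2, 8L), rup(p4td, 8L)), bw[["p3td"]], 8L)
    # bottom-up outputs
    p3out <- fuse(c(p3td, rup(p4td, 8L)), bw[["p3out"]], 8L)
    p4out <- fuse(c(p4td, rup(p5td, 16L), rdown(p3td, 16L), rdown(p3out, 16L)),
                  bw[["p4out"]], 16L)
    p4outp <- fuse(c(rdown(p3td, 16L), p4out), bw[["p4outp"]], 16L)
    levels <- c(p3out, p4out, p4outp)
    strides <- c(8L, 16L, 16L)
  }

  ch_lv <- g$ch[levels]
  head <- if (cfg$use_gscdhead) {
    nn_gscd_head(cfg$num_classes, ch_lv, hidc = a$hidc, reg_max = cfg$reg_max)
  } else {
    nn_detect(cfg$num_classes, ch_lv, reg_max = cfg$reg_max)
  }
  hd <- g_add(g, levels, head)

  structure(list(layers = g$layers, ch = g$ch, head = hd, levels = levels,
                 strides = strides, cfg = cfg),
            class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  cfg <- x$cfg
  on <- c("mixed-aggregation backbone", "bidirectional FPN", "adaptive down",
          "shared head")[c(cfg$use_femanet, cfg$use_biafa_fpn, cfg$use_adown,
                           cfg$use_gscdhead)]
  cat("<detector: ", length(x$layers), " nodes; ",
      if (length(on)) paste(on, collapse = " + ") else "baseline",
      "; strides ", paste(x$strides, collapse = "/"), ">\n", sep = "")
  invisible(x)
}

#' Run the model graph
#'
#' @param model an `sd_model`; @param x input tensor or shape probe (3,H,W,B)
#' @return per-level raw head predictions (list of `list(box, cls)`)
#' @export
forward_model <- function(model, x) {
  outs <- vector("list", length(model$layers))
  prev <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    inp <- if (length(l$from) == 1L && l$from == -1L) prev
           else if (length(l$from) == 1L) outs[[l$from]]
           else lapply(l$from, function(j) outs[[j]])
    prev <- fwd(l$m, inp)
    outs[[i]] <- prev
  }
  outs[[model$head]]
}

#' Build only the backbone of a variant
#'
#' Returns an `sd_model` whose graph stops at the stride-32 pyramid top; run
#' it with [backbone_features()] to obtain the P2..P5 feature maps. The
#' variant flags select the feature blocks and downsamplers exactly as in
#' [build_model()].
#' @param cfg a [variant_config()]
#' @return an `sd_model` without neck or head
#' @export
build_backbone <- function(cfg = variant_config()) {
  full <- build_model(cfg)
  tags <- vapply(full$layers, function(l) l$tag %||% "", character(1))
  top <- match("P5", tags)
  structure(list(layers = full$layers[seq_len(top)], ch = full$ch[seq_len(top)],
                 head = NA_integer_, levels = match(c("P2", "P3", "P4", "P5"),
                                                    tags),
                 strides = c(4L, 8L, 16L, 32L), cfg = cfg),
            class = "sd_model")
}

#' Backbone feature maps
#'
#' Runs only the backbone portion and returns the pyramid levels P2..P5.
#' @param model an `sd_model`; @param x input tensor or shape probe
#' @export
backbone_features <- function(model, x) {
  tags <- vapply(model$layers, function(l) l$tag %||% "", character(1))
  want <- match(c("P2", "P3", "P4", "P5"), tags)
  outs <- vector("list", max(want))
  prev <- x
  for (i in seq_len(max(want))) {
    l <- model$layers[[i]]
    inp <- if (length(l$from) == 1L && l$from == -1L) prev else outs[[l$from]]
    prev <- fwd(l$m, inp)
    outs[[i]] <- prev
  }
  stats::setNames(outs[want], c("P2", "P3", "P4", "P5"))
}

# ---- inference decode --------------------------------------------------------

# Anchor centres (feature units) for a level of size h x w: matrix (n, 2)
anchor_grid <- function(h, w) {
  cbind(cx = rep(seq_len(w) - 0.5, each = h), cy = rep(seq_len(h) - 0.5, w))
}

# Flatten a (C,H,W,1) prediction to an (H*W) x C matrix (column-major spatial)
flat_hw <- function(v) t(matrix(v, nrow = dim(v)[1]))

decode_level <- function(box_v, cls_v, stride, reg_max) {
  d <- dim(box_v)
  anc <- anchor_grid(d[2], d[3])
  dist <- dfl_decode(box_v, reg_max)                 # (4, H, W, 1)
  D <- flat_hw(dist)                                 # n x 4 : l, t, r, b
  P <- flat_hw(cls_v)                                # n x nc (logits)
  conf <- 1 / (1 + exp(-P))
  cls <- max.col(conf, ties.method = "first")
  data.frame(
    x1 = (anc[, "cx"] - D[, 1]) * stride, y1 = (anc[, "cy"] - D[, 2]) * stride,
    x2 = (anc[, "cx"] + D[, 3]) * stride, y2 = (anc[, "cy"] + D[, 4]) * stride,
    conf = conf[cbind(seq_len(nrow(conf)), cls)], class_id = cls - 1L)
}

#' Class-agnostic non-maximum suppression
#'
#' @param boxes tibble with x1, y1, x2, y2, conf
#' @param iou_thr suppression IoU threshold
#' @return the surviving rows, ordered by confidence
#' @export
nms_boxes <- function(boxes, iou_thr = 0.55) {
  if (nrow(boxes) == 0L) return(boxes)
  o <- order(boxes$conf, decreasing = TRUE)
  b <- boxes[o, , drop = FALSE]
  keep <- logical(nrow(b))
  area <- pmax(0, b$x2 - b$x1) * pmax(0, b$y2 - b$y1)
  alive <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(b)) break
    j <- which(alive & seq_len(nrow(b)) > i)
    if (!length(j)) next
    iw <- pmax(0, pmin(b$x2[j], b$x2[i]) - pmax(b$x1[j], b$x1[i]))
    ih <- pmax(0, pmin(b$y2[j], b$y2[i]) - pmax(b$y1[j], b$y1[i]))
    inter <- iw * ih
    iou <- inter / (area[i] + area[j] - inter)
    alive[j[iou > iou_thr]] <- FALSE
  }
  b[keep, , drop = FALSE]
}

#' Detect objects in an image
#'
#' Letterboxes the raster to the model input size, runs the network,
#' DFL-decodes the concatenated level predictions to boxes, filters by
#' confidence, applies class-agnostic NMS and clips boxes to image bounds.
#'
#' @param model an `sd_model`
#' @param image H x W x 3 numeric array (0-255) or a `labeled_image`
#' @param conf_thr confidence threshold
#' @param nms_iou NMS IoU threshold (0.55 by default)
#' @return a tibble of detections: x1, y1, x2, y2, conf, class_id (original
#'   image coordinates, half-open pixel boxes)
#' @export
forward_detect <- function(model, image, conf_thr = 0.25, nms_iou = 0.55) {
  if (inherits(image, "labeled_image")) image <- image$raster
  sz <- model$cfg$input_size
  lb <- letterbox(image, sz)
  x <- sd_tensor(array(aperm(lb$img, c(3, 1, 2)) / 255, c(3, sz, sz, 1)))
  old <- set_training(FALSE); on.exit(set_training(old))
  preds <- forward_model(model, x)
  dets <- do.call(rbind, lapply(seq_along(preds), function(i)
    decode_level(preds[[i]]$box$v, preds[[i]]$cls$v, model$strides[i],
                 model$cfg$reg_max)))
  dets <- dets[dets$conf >= conf_thr, , drop = FALSE]
  dets <- nms_boxes(dets, nms_iou)
  # map back to source image coordinates, clip
  h <- dim(image)[1]; w <- dim(image)[2]
  dets$x1 <- pmin(pmax((dets$x1 - lb$dx) / lb$scale, 0), w)
  dets$x2 <- pmin(pmax((dets$x2 - lb$dx) / lb$scale, 0), w)
  dets$y1 <- pmin(pmax((dets$y1 - lb$dy) / lb$scale, 0), h)
  dets$y2 <- pmin(pmax((dets$y2 - lb$dy) / lb$scale, 0), h)
  dets <- dets[dets$x2 > dets$x1 & dets$y2 > dets$y1, , drop = FALSE]
  tibble::as_tibble(dets)
}

#' Letterbox an image to a square canvas
#'
#' Preserves aspect ratio via nearest-neighbour resampling and pads with
#' neutral gray.
#' @param img H x W x 3 array; @param size target side; @param fill pad value
#' @return list(img, scale, dx, dy)
#' @export
letterbox <- function(img, size, fill = 114) {
  h <- dim(img)[1]; w <- dim(img)[2]
  s <- min(size / h, size / w)
  nh <- max(1L, as.integer(round(h * s))); nw <- max(1L, as.integer(round(w * s)))
  ri <- pmin(h, pmax(1L, as.integer(ceiling(seq_len(nh) / s - 1e-9))))
  ci <- pmin(w, pmax(1L, as.integer(ceiling(seq_len(nw) / s - 1e-9))))
  resized <- img[ri, ci, , drop = FALSE]
  out <- array(fill, c(size, size, 3L))
  dy <- (size - nh) %/% 2L; dx <- (size - nw) %/% 2L
  out[dy + seq_len(nh), dx + seq_len(nw), ] <- resized
  list(img = out, scale = s, dx = dx, dy = dy)
}
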