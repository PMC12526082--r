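# Detection and counting evaluation: greedy IoU matching, precision/recall,
# COCO-style AP/AR with scale breakdown, and per-image counting error metrics.
# Detections and ground truths are tibbles; multi-image sets carry an
# `image_id` column.

#' Pairwise intersection-over-union
#' @param a,b box tibbles (x1, y1, x2, y2)
#' @return matrix of IoU values, `nrow(a)` x `nrow(b)`
#' @export
box_iou <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ix <- pmax(0, outer(a$x2, b$x2, pmin) - outer(a$x1, b$x1, pmax))
  iy <- pmax(0, outer(a$y2, b$y2, pmin) - outer(a$y1, b$y1, pmax))
  inter <- ix * iy
  aa <- (a$x2 - a$x1) * (a$y2 - a$y1)
  ab <- (b$x2 - b$x1) * (b$y2 - b$y1)
  inter / (outer(aa, ab, `+`) - inter)
}

#' Greedy confidence-ordered matching of detections to ground truths
#'
#' Detections are visited in decreasing confidence; each takes the unmatched
#' ground truth with the highest IoU at or above `iou_thr`. No ground truth is
#' matched twice.
#'
#' @param dets detections (x1, y1, x2, y2, conf)
#' @param gts ground-truth boxes
#' @param iou_thr matching threshold
#' @return list: `pairs` (det row, gt row, iou), `tp`, `fp`, `fn`, and
#'   `det_matched` flags in confidence order
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  o <- order(dets$conf, decreasing = TRUE)
  dets <- dets[o, , drop = FALSE]
  iou <- box_iou(dets, gts)
  taken <- logical(nrow(gts))
  matched <- logical(nrow(dets))
  pairs <- list()
  for (i in seq_len(nrow(dets))) {
    if (!nrow(gts)) break
    cand <- which(!taken & iou[i, ] >= iou_thr)
    if (!length(cand)) next
    j <- cand[which.max(iou[i, cand])]
    taken[j] <- TRUE
    matched[i] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(det = o[i], gt = j, iou = iou[i, j])
  }
  tp <- sum(matched)
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         matrix(numeric(), 0, 3, dimnames = list(NULL, c("det", "gt", "iou"))),
       tp = tp, fp = nrow(dets) - tp, fn = nrow(gts) - tp,
       det_matched = matched, det_order = o, gt_taken = taken)
}

#' Precision and recall at one IoU threshold
#'
#' `Pr = TP / (TP + FP)` and `Re = TP / (TP + FN)`; both are 0 by convention
#' when their denominator is 0 and there are no true positives.
#'
#' @inheritParams match_detections
#' @return one-row tibble: tp, fp, fn, precision, recall
#' @export
precision_recall <- function(dets, gts, iou_thr = 0.5) {
  m <- match_detections(dets, gts, iou_thr)
  tibble::tibble(
    tp = m$tp, fp = m$fp, fn = m$fn,
    precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0,
    recall = if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0)
}

# 101-point interpolated AP from per-detection TP flags (confidence order)
# and the number of ground truths.
ap_101 <- function(tp_flags, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(tp_flags)) return(0)
  tp <- cumsum(tp_flags)
  fp <- cumsum(!tp_flags)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  # precision envelope (monotone non-increasing from the right)
  prec <- rev(cummax(rev(prec)))
  grid <- seq(0, 1, by = 0.01)
  idx <- findInterval(grid, rec, left.open = TRUE) + 1L
  p <- ifelse(idx <= length(prec), prec[idx], 0)
  mean(p)
}

# Split a multi-image tibble into per-image list keyed by image_id.
split_images <- function(x, ids) {
  if (!nrow(x)) return(stats::setNames(list(), character(0)))
  split(x, factor(x$image_id, levels = ids))
}

#' COCO-style average precision and recall
#'
#' 101-point interpolated AP, averaged over the IoU grid 0.50:0.95 (step
#' 0.05). `AP@50` uses IoU 0.50 only. Scale-restricted variants keep only
#' ground truths of one scale category; detections matched to out-of-scale
#' ground truths, or unmatched detections of out-of-scale size, are ignored
#' rather than counted as false positives (COCO convention). AR is the mean
#' over the IoU grid of the maximum recall with at most `max_det` detections
#' per image.
#'
#' @param dets detections over one or more images (x1, y1, x2, y2, conf,
#'   optional image_id)
#' @param gts ground-truth boxes (x1, y1, x2, y2, optional image_id)
#' @param iou_thrs IoU thresholds (default COCO grid)
#' @param scale_filter NULL or one of "small", "medium", "large"
#' @param native_size,eval_size scale-category resolution handling, see
#'   [categorize_scale()]
#' @param max_det per-image detection cap for AP and AR
#' @return scalar AP (or a tibble via [eval_detections()])
#' @export
average_precision <- function(dets, gts, iou_thrs = seq(0.5, 0.95, by = 0.05),
                              scale_filter = NULL, native_size = 640,
                              eval_size = 640, max_det = 300L) {
  prep <- prep_eval(dets, gts, scale_filter, native_size, eval_size, max_det)
  mean(vapply(iou_thrs, function(th) ap_at(prep, th), numeric(1)), na.rm = TRUE)
}

# Shared preprocessing: per-image det/gt lists plus in-scale flags.
prep_eval <- function(dets, gts, scale_filter, native_size, eval_size, max_det) {
  if (!"image_id" %in% names(dets)) dets$image_id <- 1L
  if (!"image_id" %in% names(gts)) gts$image_id <- 1L
  ids <- sort(unique(c(dets$image_id, gts$image_id)))
  dl <- split_images(dets, ids); gl <- split_images(gts, ids)
  per_img <- lapply(ids, function(id) {
    d <- dl[[as.character(id)]] %||% dets[0, , drop = FALSE]
    g <- gl[[as.character(id)]] %||% gts[0, , drop = FALSE]
    d <- d[order(d$conf, decreasing = TRUE), , drop = FALSE]
    if (nrow(d) > max_det) d <- d[seq_len(max_det), , drop = FALSE]
    keep_g <- if (is.null(scale_filter)) rep(TRUE, nrow(g)) else
      as.character(categorize_scale(g, native_size = native_size,
                                    eval_size = eval_size)) == scale_filter
    keep_d <- if (is.null(scale_filter)) rep(TRUE, nrow(d)) else
      as.character(categorize_scale(d, native_size = native_size,
                                    eval_size = eval_size)) == scale_filter
    list(d = d, g = g, keep_g = keep_g, keep_d = keep_d)
  })
  list(per_img = per_img)
}

# AP at a single IoU threshold from prepped per-image data.
ap_at <- function(prep, th, want_recall = FALSE) {
  confs <- numeric(0); flags <- logical(0); n_gt <- 0L
  for (pi in prep$per_img) {
    d <- pi$d; g <- pi$g
    n_gt <- n_gt + sum(pi$keep_g)
    if (!nrow(d)) next
    iou <- box_iou(d, g)
    taken <- logical(nrow(g))
    for (i in seq_len(nrow(d))) {
      cand <- if (nrow(g)) which(!taken & iou[i, ] >= th) else integer(0)
      if (length(cand)) {
        # prefer in-scale ground truths, mirroring COCO's ignore ordering
        cin <- cand[pi$keep_g[cand]]
        j <- if (length(cin)) cin[which.max(iou[i, cin])] else
          cand[which.max(iou[i, cand])]
        taken[j] <- TRUE
        if (pi$keep_g[j]) {
          confs <- c(confs, d$conf[i]); flags <- c(flags, TRUE)
        }                      # matched to ignored gt -> dropped entirely
      } else if (pi$keep_d[i]) {
        confs <- c(confs, d$conf[i]); flags <- c(flags, FALSE)
      }                        # unmatched + out-of-scale -> ignored
    }
  }
  o <- order(confs, decreasing = TRUE)
  if (want_recall) {
    if (n_gt == 0L) return(NA_real_)
    return(sum(flags) / n_gt)
  }
  ap_101(flags[o], n_gt)
}

#' Average recall over the IoU grid
#' @inheritParams average_precision
#' @export
average_recall <- function(dets, gts, iou_thrs = seq(0.5, 0.95, by = 0.05),
                           scale_filter = NULL, native_size = 640,
                           eval_size = 640, max_det = 300L) {
  prep <- prep_eval(dets, gts, scale_filter, native_size, eval_size, max_det)
  mean(vapply(iou_thrs, function(th) ap_at(prep, th, want_recall = TRUE),
              numeric(1)), na.rm = TRUE)
}

#' Full COCO-style detection evaluation
#'
#' @inheritParams average_precision
#' @return a `spike_eval` tibble with ap, ap50, ap_small, ap_medium,
#'   ap_large, ar
#' @export
eval_detections <- function(dets, gts, native_size = 640, eval_size = 640,
                            max_det = 300L) {
  out <- tibble::tibble(
    ap = average_precision(dets, gts, native_size = native_size,
                           eval_size = eval_size, max_det = max_det),
    ap50 = average_precision(dets, gts, iou_thrs = 0.5,
                             native_size = native_size, eval_size = eval_size,
                             max_det = max_det),
    ap_small = average_precision(dets, gts, scale_filter = "small",
                                 native_size = native_size,
                                 eval_size = eval_size, max_det = max_det),
    ap_medium = average_precision(dets, gts, scale_filter = "medium",
                                  native_size = native_size,
                                  eval_size = eval_size, max_det = max_det),
    ap_large = average_precision(dets, gts, scale_filter = "large",
                                 native_size = native_size,
                                 eval_size = eval_size, max_det = max_det),
    ar = average_recall(dets, gts, native_size = native_size,
                        eval_size = eval_size, max_det = max_det))
  class(out) <- c("spike_eval", class(out))
  out
}

#' Counting error metrics
#'
#' Mean absolute error, root-mean-square error and the coefficient of
#' determination between true and predicted per-image counts:
#' `R^2 = 1 - SS_res / SS_tot`. R-squared can be negative for predictors worse
#' than the mean, and is undefined (NA) when the true counts have zero
#' variance.
#'
#' @param y true per-image counts (non-negative)
#' @param y_hat predicted counts, same length
#' @return a `count_metrics` tibble: n, mae, rmse, r2
#' @export
count_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1L, all(y >= 0),
            all(y_hat >= 0))
  e <- y - y_hat
  sstot <- sum((y - mean(y))^2)
  r2 <- if (length(y) >= 2L && sstot > 0) 1 - sum(e^2) / sstot else NA_real_
  out <- tibble::tibble(n = length(y), mae = mean(abs(e)),
                        rmse = sqrt(mean(e^2)), r2 = r2)
  class(out) <- c("count_metrics", class(out))
  out
}

#' Count detections above a confidence threshold
#'
#' Bridges detection output to the counting task: the predicted spike count of
#' an image is the number of post-NMS detections with confidence at or above
#' `conf_thr`.
#'
#' @param dets detection tibble with a conf column (optionally image_id)
#' @param conf_thr counting confidence threshold (default 0.25)
#' @return integer count, or a tibble of counts per image_id
#' @export
detections_to_count <- function(dets, conf_thr = 0.25) {
  keep <- dets$conf >= conf_thr
  if (!"image_id" %in% names(dets)) return(sum(keep))
  dplyr::count(dets[keep, , drop = FALSE], .data$image_id, name = "count")
}

# ---- tidiers ----------------------------------------------------------------

#' Tidy a result object
#' @param x object; @param ... unused
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a result object
#' @param x object; @param ... unused
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy.spike_eval <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}

#' @export
glance.spike_eval <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.count_metrics <- function(x, ...) {
  tibble::tibble(metric = c("mae", "rmse", "r2"),
                 value = c(x$mae, x$rmse, x$r2))
}

#' @export
glance.count_metrics <- function(x, ...) tibble::as_tibble(x)
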