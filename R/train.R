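# Training: task-aligned assignment, the composite detection loss (IoU box
# loss + distribution-focal loss + binary cross-entropy), analytic gradients
# seeded into the reverse-mode tape, and SGD with momentum.

# Anchor centres and strides for every level, in feature units and pixels.
make_anchors <- function(level_dims, strides) {
  anc <- do.call(rbind, lapply(seq_along(strides), function(i) {
    d <- level_dims[[i]]
    cbind(anchor_grid(d[1], d[2]), stride = strides[i])
  }))
  anc
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

# Distance-IoU loss (1 - IoU + centre-distance penalty) and its gradient with
# respect to the predicted corners. Boxes are matrices (n, 4) = x1,y1,x2,y2.
diou_loss_grad <- function(p, g) {
  px1 <- p[, 1]; py1 <- p[, 2]; px2 <- p[, 3]; py2 <- p[, 4]
  gx1 <- g[, 1]; gy1 <- g[, 2]; gx2 <- g[, 3]; gy2 <- g[, 4]
  iw <- pmax(pmin(px2, gx2) - pmax(px1, gx1), 0)
  ih <- pmax(pmin(py2, gy2) - pmax(py1, gy1), 0)
  I <- iw * ih
  ap <- pmax(px2 - px1, 0) * pmax(py2 - py1, 0)
  ag <- (gx2 - gx1) * (gy2 - gy1)
  U <- ap + ag - I
  iou <- ifelse(U > 0, I / U, 0)
  # enclosing box diagonal and centre distance
  cw <- pmax(px2, gx2) - pmin(px1, gx1)
  ch <- pmax(py2, gy2) - pmin(py1, gy1)
  c2 <- cw^2 + ch^2 + 1e-9
  dx <- (px1 + px2 - gx1 - gx2) / 2
  dy <- (py1 + py2 - gy1 - gy2) / 2
  rho2 <- dx^2 + dy^2
  loss <- 1 - iou + rho2 / c2
  # gradients
  gI <- cbind(-ih * (px1 > gx1), -iw * (py1 > gy1),
              ih * (px2 < gx2), iw * (py2 < gy2))
  gAp <- cbind(-(py2 - py1), -(px2 - px1), py2 - py1, px2 - px1)
  gU <- gAp - gI
  d_iou <- (gI * U - I * gU) / pmax(U^2, 1e-9)
  # centre-distance term
  d_rho <- cbind(dx, dy, dx, dy)
  d_cw <- cbind(-(px1 < gx1), 0, (px2 > gx2), 0) * 2 * cw
  d_ch <- cbind(0, -(py1 < gy1), 0, (py2 > gy2)) * 2 * ch
  d_pen <- d_rho / c2 - rho2 / c2^2 * (d_cw + d_ch)
  grad <- -d_iou + d_pen
  dimnames(grad) <- NULL
  list(loss = loss, iou = iou, grad = grad)
}

# Task-aligned assignment for one image.
# scores: (N,) sigmoid class score (single class); pboxes (N,4) px;
# anchors (N,3) cx, cy, stride; gt (M,4). Returns assignment vectors.
tal_assign <- function(scores, pboxes, anchors, gt, topk = 10L,
                       alpha = 0.5, beta = 6.0) {
  N <- nrow(anchors); M <- nrow(gt)
  if (M == 0L) return(list(gt_idx = integer(N), tscore = numeric(N)))
  acx <- anchors[, 1] * anchors[, 3]
  acy <- anchors[, 2] * anchors[, 3]
  inside <- outer(acx, gt[, 1], `>`) & outer(acx, gt[, 3], `<`) &
            outer(acy, gt[, 2], `>`) & outer(acy, gt[, 4], `<`)   # N x M
  iou <- box_iou(as_box_df(pboxes), as_box_df(gt))                 # N x M
  metric <- (pmax(scores, 1e-9)^alpha) * (pmax(iou, 0)^beta)
  metric[!inside] <- 0
  chosen <- matrix(FALSE, N, M)
  for (j in seq_len(M)) {
    cand <- which(metric[, j] > 0)
    if (!length(cand)) next
    top <- cand[order(metric[cand, j], decreasing = TRUE)]
    chosen[top[seq_len(min(topk, length(top)))], j] <- TRUE
  }
  gt_idx <- integer(N); tscore <- numeric(N)
  for (i in which(rowSums(chosen) > 0)) {
    js <- which(chosen[i, ])
    j <- js[which.max(metric[i, js])]
    gt_idx[i] <- j
  }
  # normalized target scores per gt: metric * max_iou / max_metric
  for (j in seq_len(M)) {
    sel <- which(gt_idx == j)
    if (!length(sel)) next
    mm <- max(metric[sel, j]); mi <- max(iou[sel, j])
    tscore[sel] <- if (mm > 0) metric[sel, j] * mi / mm else 0
  }
  list(gt_idx = gt_idx, tscore = tscore)
}

as_box_df <- function(m) {
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
}

# Composite detection loss and output-gradient seeds for one batch.
# preds: per-level list(box, cls) tensors; gt_list: per-image box tibbles
# (pixel coords at network input scale).
detect_loss <- function(preds, gt_list, strides, reg_max, nc = 1L,
                        gain = c(box = 7.5, cls = 0.5, dfl = 1.5)) {
  nl <- length(preds)
  level_dims <- lapply(preds, function(p) dim(p$box$v)[2:3])
  B <- dim(preds[[1]]$box$v)[4]
  anc <- make_anchors(level_dims, strides)
  N <- nrow(anc)
  n_per <- vapply(level_dims, prod, numeric(1))
  box_grads <- lapply(preds, function(p) array(0, dim(p$box$v)))
  cls_grads <- lapply(preds, function(p) array(0, dim(p$cls$v)))
  tot <- c(box = 0, cls = 0, dfl = 0)
  bins <- 0:(reg_max - 1L)
  for (b in seq_len(B)) {
    # flatten predictions for image b: D (N, 4*reg_max), Z (N, nc)
    D <- do.call(rbind, lapply(preds, function(p)
      flat_hw(p$box$v[, , , b, drop = FALSE])))
    Z <- do.call(rbind, lapply(preds, function(p)
      flat_hw(p$cls$v[, , , b, drop = FALSE])))
    # bin probabilities: channels are side-major blocks of reg_max bins,
    # so (anchor, bin, side) indexing is a straight column-major reshape
    P <- array(D, c(N, reg_max, 4L))
    # numerically stable softmax per (anchor, side)
    for (s in 1:4) {
      M <- P[, , s]
      M <- exp(M - apply(M, 1, max))
      P[, , s] <- M / rowSums(M)
    }
    dist <- sapply(1:4, function(s) P[, , s] %*% bins)   # N x 4, feature units
    px <- cbind((anc[, 1] - dist[, 1]), (anc[, 2] - dist[, 2]),
                (anc[, 1] + dist[, 3]), (anc[, 2] + dist[, 4])) * anc[, 3]
    sc <- sigmoid_(Z[, 1])
    gt <- gt_list[[b]]
    gtm <- if (nrow(gt)) cbind(gt$x1, gt$y1, gt$x2, gt$y2) else
      matrix(numeric(), 0, 4)
    asg <- tal_assign(sc, px, anc, gtm)
    tsum <- max(sum(asg$tscore), 1)
    # classification BCE over all anchors
    tgt <- asg$tscore
    tot["cls"] <- tot["cls"] - gain["cls"] *
      sum(tgt * log(pmax(sc, 1e-12)) + (1 - tgt) * log(pmax(1 - sc, 1e-12))) / tsum
    gz <- gain["cls"] * (sc - tgt) / tsum                 # dBCE/dlogit
    # box + dfl on assigned anchors
    pos <- which(asg$gt_idx > 0)
    gd_full <- matrix(0, N, 4 * reg_max)
    if (length(pos)) {
      gsel <- gtm[asg$gt_idx[pos], , drop = FALSE]
      wgt <- asg$tscore[pos] / tsum
      dl <- diou_loss_grad(px[pos, , drop = FALSE], gsel)
      tot["box"] <- tot["box"] + gain["box"] * sum(dl$loss * wgt)
      # chain: corners -> distances (l,t,r,b) -> bin logits via softmax E
      sgn <- c(-1, -1, 1, 1)
      tdist <- cbind(anc[pos, 1] - gsel[, 1] / anc[pos, 3],
                     anc[pos, 2] - gsel[, 2] / anc[pos, 3],
                     gsel[, 3] / anc[pos, 3] - anc[pos, 1],
                     gsel[, 4] / anc[pos, 3] - anc[pos, 2])
      tdist <- pmin(pmax(tdist, 0), reg_max - 1 - 0.01)
      for (s in 1:4) {
        # box-loss gradient through the DFL expectation
        dE <- gain["box"] * wgt * dl$grad[, s] * sgn[s] * anc[pos, 3]
        Ppos <- P[pos, , s, drop = FALSE][, , 1]
        if (length(pos) == 1L) Ppos <- matrix(Ppos, 1)
        Epos <- as.vector(Ppos %*% bins)
        gl <- Ppos * (matrix(bins, length(pos), reg_max, byrow = TRUE) - Epos) * dE
        # DFL cross-entropy on the two adjacent bins
        lo <- floor(tdist[, s]); hi <- lo + 1
        wlo <- hi - tdist[, s]; whi <- tdist[, s] - lo
        plo <- Ppos[cbind(seq_along(pos), lo + 1L)]
        phi <- Ppos[cbind(seq_along(pos), pmin(hi, reg_max - 1) + 1L)]
        tot["dfl"] <- tot["dfl"] - gain["dfl"] *
          sum(wgt * (wlo * log(pmax(plo, 1e-12)) + whi * log(pmax(phi, 1e-12))))
        tmix <- matrix(0, length(pos), reg_max)
        tmix[cbind(seq_along(pos), lo + 1L)] <- wlo
        tmix[cbind(seq_along(pos), pmin(hi, reg_max - 1) + 1L)] <-
          tmix[cbind(seq_along(pos), pmin(hi, reg_max - 1) + 1L)] + whi
        gl <- gl + gain["dfl"] * wgt * (Ppos - tmix)
        gd_full[pos, (s - 1L) * reg_max + seq_len(reg_max)] <- gl
      }
    }
    # scatter gradients back into per-level (C,h,w) arrays
    at <- 0L
    for (i in seq_len(nl)) {
      idx <- at + seq_len(n_per[i])
      d <- level_dims[[i]]
      box_grads[[i]][, , , b] <- array(t(gd_full[idx, , drop = FALSE]),
                                       c(4L * reg_max, d[1], d[2]))
      cls_grads[[i]][, , , b] <- array(t(matrix(gz[idx], ncol = 1)),
                                       c(nc, d[1], d[2]))
      at <- at + n_per[i]
    }
  }
  seeds <- list()
  for (i in seq_len(nl)) {
    seeds[[length(seeds) + 1L]] <- list(t = preds[[i]]$box, g = box_grads[[i]] / B)
    seeds[[length(seeds) + 1L]] <- list(t = preds[[i]]$cls, g = cls_grads[[i]] / B)
  }
  list(loss = sum(tot) / B, parts = tot / B, seeds = seeds)
}

# ---- optimizer ---------------------------------------------------------------

new_sgd <- function(params, lr = 0.01, momentum = 0.937, weight_decay = 5e-4) {
  list(params = params, lr = lr, momentum = momentum, wd = weight_decay,
       vel = lapply(params, function(p) array(0, dim(p$v))))
}

sgd_step <- function(opt) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (opt$wd > 0 && length(dim(p$v)) == 4L && dim(p$v)[2] > 0 &&
        prod(dim(p$v)) > length(p$v) / prod(dim(p$v)) && dim(p$v)[1] > 1)
      g <- g + opt$wd * p$v
    opt$vel[[i]] <- opt$momentum * opt$vel[[i]] - opt$lr * g
    p$v <- p$v + opt$vel[[i]]
    p$grad <- NULL
  }
  opt
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' Train a detector on labeled images
#'
#' Minimal SGD training loop over letterboxed images with the composite
#' detection loss (distance-IoU box loss, distribution-focal loss, and binary
#' cross-entropy under task-aligned assignment). Defaults follow the published
#' training recipe: batch size 8, learning rate 0.01, SGD momentum 0.937.
#'
#' @param model an `sd_model`
#' @param images list of [labeled_image()]
#' @param epochs training epochs
#' @param batch_size images per step
#' @param lr,momentum,weight_decay SGD hyper-parameters
#' @param seed RNG seed for shuffling
#' @param verbose print per-epoch loss
#' @return list: `model` (weights updated in place), `history` tibble of
#'   per-epoch mean losses
#' @export
train_model <- function(model, images, epochs = 10L, batch_size = 8L,
                        lr = 0.01, momentum = 0.937, weight_decay = 5e-4,
                        seed = 0L, verbose = FALSE) {
  params <- unlist(lapply(model$layers, function(l) collect_params(l$m)),
                   recursive = FALSE)
  opt <- new_sgd(params, lr, momentum, weight_decay)
  sz <- model$cfg$input_size
  prep <- lapply(images, function(im) {
    lb <- letterbox(im$raster, sz)
    bx <- im$boxes
    b <- if (nrow(bx)) cbind(bx$x1, bx$y1, bx$x2, bx$y2) * lb$scale +
      matrix(c(lb$dx, lb$dy, lb$dx, lb$dy), nrow(bx), 4, byrow = TRUE)
      else matrix(numeric(), 0, 4)
    list(x = aperm(lb$img, c(3, 1, 2)) / 255,
         gt = boxes_from_matrix(b))
  })
  hist <- list()
  old <- set_training(TRUE)
  on.exit(set_training(old))
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(prep))
      losses <- c()
      for (s in seq(1, length(ord), by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, length(ord))]
        xb <- array(0, c(3L, sz, sz, length(idx)))
        for (k in seq_along(idx)) xb[, , , k] <- prep[[idx[k]]]$x
        x <- sd_tensor(xb)
        preds <- with_tape(forward_model(model, x))
        ls <- detect_loss(preds, lapply(prep[idx], `[[`, "gt"),
                          model$strides, model$cfg$reg_max,
                          model$cfg$num_classes)
        sd_backward(ls$seeds)
        opt <- sgd_step(opt)
        losses <- c(losses, ls$loss)
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses))
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, mean(losses)))
    }
  })
  list(model = model, history = dplyr::bind_rows(hist))
}

boxes_from_matrix <- function(m) {
  if (!nrow(m)) return(boxes_tbl())
  boxes_tbl(m[, 1], m[, 2], m[, 3], m[, 4], 0L)
}
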