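# Minimal reverse-mode tensor layer.
#
# Activations are dense arrays with dim (C, H, W, B), channel-fastest so the
# C++ GEMM kernels write channels contiguously. Two tensor flavours flow
# through the same forward code:
#   * sd_tensor — an environment holding $v (the array), $grad, and $rg
#     (requires gradient). Ops executed while a tape is recording push a
#     backward closure, giving reverse-mode differentiation.
#   * sd_shape  — a shape-only probe carrying dims and a MAC accumulator,
#     used by the complexity auditor to trace FLOPs without arithmetic.

.sd_env <- new.env(parent = emptyenv())
.sd_env$rec <- FALSE
.sd_env$tape <- NULL
.sd_env$training <- FALSE

#' Create a tensor
#'
#' Wraps a numeric array of dim (C, H, W, B) as a tensor the network ops
#' understand. Batched image data enters the network through this call.
#'
#' @param v numeric array; dims are padded to length 4 (C, H, W, B).
#' @param requires_grad should gradients be accumulated for this tensor?
#' @return an `sd_tensor`
#' @export
sd_tensor <- function(v, requires_grad = FALSE) {
  if (is.null(dim(v))) dim(v) <- c(length(v), 1L, 1L, 1L)
  d <- dim(v)
  if (length(d) < 4L) dim(v) <- c(d, rep(1L, 4L - length(d)))
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$grad <- NULL
  t$rg <- isTRUE(requires_grad)
  class(t) <- "sd_tensor"
  t
}

sd_param <- function(v) sd_tensor(v, requires_grad = TRUE)

#' @export
print.sd_tensor <- function(x, ...) {
  cat("<sd_tensor ", paste(dim(x$v), collapse = "x"),
      if (x$rg) " (param)" else "", ">\n", sep = "")
  invisible(x)
}

#' Shape probe for tracing
#'
#' A stand-in tensor carrying only (C, H, W, B) dims plus a multiply-
#' accumulate counter; running the forward graph on one of these yields the
#' FLOP audit without any arithmetic.
#'
#' @param c,h,w,b dims
#' @param tracer an environment with a `$macs` field (see [new_tracer()])
#' @return an `sd_shape`
#' @export
sd_shape <- function(c, h, w, b = 1L, tracer = NULL) {
  structure(list(dims = c(C = as.integer(c), H = as.integer(h),
                          W = as.integer(w), B = as.integer(b)),
                 tracer = tracer),
            class = "sd_shape")
}

#' @rdname sd_shape
#' @export
new_tracer <- function() {
  e <- new.env(parent = emptyenv())
  e$macs <- 0
  e
}

is_shape <- function(x) inherits(x, "sd_shape")

shape_like <- function(x, c = NULL, h = NULL, w = NULL) {
  d <- x$dims
  sd_shape(c %||% d[["C"]], h %||% d[["H"]], w %||% d[["W"]], d[["B"]],
           tracer = x$tracer)
}

trace_macs <- function(x, m) {
  if (!is.null(x$tracer)) x$tracer$macs <- x$tracer$macs + m
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tape ------------------------------------------------------------------

tape_active <- function() isTRUE(.sd_env$rec)

#' Record a forward pass for backpropagation
#'
#' Evaluates `expr` with the gradient tape enabled; call [sd_backward()]
#' afterwards to propagate gradients into parameters.
#' @param expr forward computation
#' @export
with_tape <- function(expr) {
  .sd_env$tape <- vector("list", 0L)
  .sd_env$rec <- TRUE
  on.exit(.sd_env$rec <- FALSE)
  expr
}

push_node <- function(out, bw) {
  if (tape_active()) .sd_env$tape[[length(.sd_env$tape) + 1L]] <- list(out = out, bw = bw)
  out
}

add_grad <- function(t, g) {
  if (is.null(t)) return(invisible(NULL))
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

#' Backpropagate from seeded outputs
#'
#' @param seeds list of `list(t = tensor, g = gradient array)` pairs; gradients
#'   are accumulated into every parameter reached by the recorded tape.
#' @export
sd_backward <- function(seeds) {
  for (s in seeds) add_grad(s$t, s$g)
  tape <- .sd_env$tape
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (!is.null(n$out$grad)) n$bw(n$out$grad)
  }
  .sd_env$tape <- NULL
  invisible(NULL)
}

set_training <- function(on) {
  old <- .sd_env$training
  .sd_env$training <- isTRUE(on)
  invisible(old)
}
is_training <- function() isTRUE(.sd_env$training)

# ---- primitive ops ---------------------------------------------------------

autopad <- function(k) as.integer(k %/% 2)

conv_out_hw <- function(h, w, k, s, p) {
  c(h = (h + 2L * p - k) %/% s + 1L, w = (w + 2L * p - k) %/% s + 1L)
}

#' 2-D convolution
#'
#' @param x input tensor or shape probe, (C,H,W,B)
#' @param w weight parameter, dim (C_in/groups, kh, kw, C_out)
#' @param bias optional bias parameter of length C_out
#' @param stride,pad,groups usual convolution hyper-parameters
#' @export
op_conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L, groups = 1L) {
  wd <- dim(w$v)
  k <- wd[2]; co <- wd[4]
  if (is_shape(x)) {
    hw <- conv_out_hw(x$dims[["H"]], x$dims[["W"]], k, stride, pad)
    out <- sd_shape(co, hw[["h"]], hw[["w"]], x$dims[["B"]], tracer = x$tracer)
    trace_macs(x, as.double(wd[1]) * wd[2] * wd[3] * co *
                 hw[["h"]] * hw[["w"]] * x$dims[["B"]])
    return(out)
  }
  stopifnot(dim(x$v)[1] == wd[1] * groups)
  v <- cpp_conv2d(x$v, w$v, as.integer(stride), as.integer(pad), as.integer(groups))
  if (!is.null(bias)) v <- v + as.vector(bias$v)  # recycles down channel dim
  out <- sd_tensor(v)
  if (tape_active()) {
    H <- dim(x$v)[2]; W <- dim(x$v)[3]
    push_node(out, function(g) {
      add_grad(x, cpp_conv2d_bwx(g, w$v, as.integer(stride), as.integer(pad),
                                 as.integer(groups), H, W))
      add_grad(w, cpp_conv2d_bww(x$v, g, wd[2], wd[3], as.integer(stride),
                                 as.integer(pad), as.integer(groups)))
      if (!is.null(bias)) add_grad(bias, rowSums(matrix(g, nrow = co)))
    })
  }
  out
}

#' Batch normalization (training uses batch statistics)
#' @param x input
#' @param bn a bn state environment with gamma/beta params and running stats
#' @param eps variance floor
#' @export
op_bn <- function(x, bn, eps = 1e-5) {
  if (is_shape(x)) return(x)
  C <- dim(x$v)[1]
  M <- matrix(x$v, nrow = C)
  n <- ncol(M)
  if (is_training()) {
    mu <- rowMeans(M)
    va <- rowMeans((M - mu)^2)
    bn$rmean <- 0.97 * bn$rmean + 0.03 * mu
    bn$rvar <- 0.97 * bn$rvar + 0.03 * va * n / max(n - 1, 1)
  } else {
    mu <- bn$rmean
    va <- bn$rvar
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (M - mu) * istd
  v <- array(bn$gamma$v[, 1, 1, 1] * xhat + bn$beta$v[, 1, 1, 1], dim(x$v))
  out <- sd_tensor(v)
  if (tape_active()) {
    train <- is_training()
    push_node(out, function(g) {
      G <- matrix(g, nrow = C)
      gam <- bn$gamma$v[, 1, 1, 1]
      add_grad(bn$gamma, array(rowSums(G * xhat), dim(bn$gamma$v)))
      add_grad(bn$beta, array(rowSums(G), dim(bn$beta$v)))
      if (train) {
        gx <- (gam * istd) * (G - rowMeans(G) - xhat * rowMeans(G * xhat))
      } else {
        gx <- (gam * istd) * G
      }
      add_grad(x, array(gx, dim(x$v)))
    })
  }
  out
}

#' Group normalization
#'
#' Normalizes each channel group within each sample, then applies a learnable
#' per-channel affine transform. With `groups = C` this is per-channel
#' (instance) normalization, the convention used in the shared detection head.
#' @param x input
#' @param gamma,beta per-channel affine parameters
#' @param groups number of channel groups; must divide C
#' @param eps variance floor
#' @export
op_gn <- function(x, gamma, beta, groups, eps = 1e-5) {
  if (is_shape(x)) {
    if (x$dims[["C"]] %% groups != 0L)
      stop("group_norm: `groups` must divide the channel count")
    return(x)
  }
  d <- dim(x$v)
  C <- d[1]
  if (C %% groups != 0L) stop("group_norm: `groups` must divide the channel count")
  cg <- C %/% groups
  # (C,H,W,B) -> (Cg, g, HW, B) -> stats per (g, B) column
  xg <- array(x$v, c(cg, groups, d[2] * d[3], d[4]))
  xp <- aperm(xg, c(1, 3, 2, 4))                    # (Cg, HW, g, B)
  M <- matrix(xp, nrow = cg * d[2] * d[3])          # rows: within-group elems
  mu <- colMeans(M)
  va <- colMeans(M^2) - mu^2
  istd <- 1 / sqrt(pmax(va, 0) + eps)
  xhat_p <- sweep(sweep(M, 2, mu), 2, istd, `*`)
  xhat <- aperm(array(xhat_p, c(cg, d[2] * d[3], groups, d[4])), c(1, 3, 2, 4))
  xhat <- array(xhat, d)
  gam <- gamma$v[, 1, 1, 1]
  v <- xhat * gam + beta$v[, 1, 1, 1]               # recycles down channels
  out <- sd_tensor(v)
  if (tape_active()) {
    push_node(out, function(g) {
      add_grad(gamma, array(rowSums(matrix(g * xhat, nrow = C)), dim(gamma$v)))
      add_grad(beta, array(rowSums(matrix(g, nrow = C)), dim(beta$v)))
      gxh <- g * gam
      gp <- matrix(aperm(array(gxh, c(cg, groups, d[2] * d[3], d[4])),
                         c(1, 3, 2, 4)), nrow = cg * d[2] * d[3])
      gx_p <- sweep(gp - matrix(colMeans(gp), nrow(gp), ncol(gp), byrow = TRUE) -
                      xhat_p * matrix(colMeans(gp * xhat_p), nrow(gp), ncol(gp),
                                      byrow = TRUE),
                    2, istd, `*`)
      gx <- aperm(array(gx_p, c(cg, d[2] * d[3], groups, d[4])), c(1, 3, 2, 4))
      add_grad(x, array(gx, d))
    })
  }
  out
}

#' SiLU activation
#' @param x input
#' @export
op_silu <- function(x) {
  if (is_shape(x)) return(x)
  s <- 1 / (1 + exp(-x$v))
  out <- sd_tensor(x$v * s)
  if (tape_active()) {
    xv <- x$v
    push_node(out, function(g) add_grad(x, g * (s * (1 + xv * (1 - s)))))
  }
  out
}

#' Sigmoid activation
#' @param x input
#' @export
op_sigmoid <- function(x) {
  if (is_shape(x)) return(x)
  s <- 1 / (1 + exp(-x$v))
  out <- sd_tensor(s)
  if (tape_active()) push_node(out, function(g) add_grad(x, g * s * (1 - s)))
  out
}

#' Elementwise addition (identical shapes)
#' @param x,y inputs
#' @export
op_add <- function(x, y) {
  if (is_shape(x)) {
    stopifnot(identical(unname(x$dims), unname(y$dims)))
    return(x)
  }
  out <- sd_tensor(x$v + y$v)
  if (tape_active()) push_node(out, function(g) { add_grad(x, g); add_grad(y, g) })
  out
}

#' Broadcast multiply by a single-channel spatial map
#'
#' `w` has one channel and the same (H, W, B) as `x`; used to apply a spatial
#' attention weight map to every channel.
#' @param x input; @param w weight map tensor (1,H,W,B)
#' @export
op_mul_spatial <- function(x, w) {
  if (is_shape(x)) return(x)
  d <- dim(x$v)
  wm <- array(rep(w$v, each = d[1]), d)
  out <- sd_tensor(x$v * wm)
  if (tape_active()) {
    push_node(out, function(g) {
      add_grad(x, g * wm)
      gw <- colSums(matrix(g * x$v, nrow = d[1]))
      add_grad(w, array(gw, dim(w$v)))
    })
  }
  out
}

#' Multiply by a learnable scalar
#' @param x input; @param s scalar parameter tensor
#' @export
op_scale <- function(x, s) {
  if (is_shape(x)) return(x)
  out <- sd_tensor(x$v * s$v[1])
  if (tape_active()) {
    sv <- s$v[1]
    push_node(out, function(g) {
      add_grad(x, g * sv)
      add_grad(s, array(sum(g * x$v), dim(s$v)))
    })
  }
  out
}

#' Concatenate along the channel axis
#' @param xs list of tensors with matching (H,W,B)
#' @export
op_concat <- function(xs) {
  if (is_shape(xs[[1]])) {
    cs <- vapply(xs, function(x) x$dims[["C"]], integer(1))
    return(shape_like(xs[[1]], c = sum(cs)))
  }
  vs <- lapply(xs, function(x) x$v)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[1], integer(1))
  tot <- sum(cs)
  v <- array(0, c(tot, d1[2], d1[3], d1[4]))
  at <- 0L
  for (i in seq_along(vs)) {
    v[at + seq_len(cs[i]), , , ] <- vs[[i]]
    at <- at + cs[i]
  }
  out <- sd_tensor(v)
  if (tape_active()) {
    push_node(out, function(g) {
      at <- 0L
      for (i in seq_along(xs)) {
        add_grad(xs[[i]], g[at + seq_len(cs[i]), , , , drop = FALSE])
        at <- at + cs[i]
      }
    })
  }
  out
}

#' Slice a channel range
#' @param x input; @param from,to 1-based channel bounds (inclusive)
#' @export
op_slice_c <- function(x, from, to) {
  if (is_shape(x)) return(shape_like(x, c = to - from + 1L))
  out <- sd_tensor(x$v[from:to, , , , drop = FALSE])
  if (tape_active()) {
    d <- dim(x$v)
    push_node(out, function(g) {
      gx <- array(0, d)
      gx[from:to, , , ] <- g
      add_grad(x, gx)
    })
  }
  out
}

#' Max pooling
#' @param x input; @param k,stride,pad window, stride and padding
#' @export
op_maxpool <- function(x, k, stride = k, pad = 0L) {
  if (is_shape(x)) {
    hw <- conv_out_hw(x$dims[["H"]], x$dims[["W"]], k, stride, pad)
    return(shape_like(x, h = hw[["h"]], w = hw[["w"]]))
  }
  r <- cpp_maxpool(x$v, as.integer(k), as.integer(stride), as.integer(pad))
  out <- sd_tensor(r$out)
  if (tape_active()) {
    xdim <- dim(x$v)
    push_node(out, function(g) add_grad(x, cpp_maxpool_bw(g, r$idx, xdim)))
  }
  out
}

#' Average pooling
#' @param x input; @param k,stride,pad window, stride and padding
#' @export
op_avgpool <- function(x, k, stride = k, pad = 0L) {
  if (is_shape(x)) {
    hw <- conv_out_hw(x$dims[["H"]], x$dims[["W"]], k, stride, pad)
    return(shape_like(x, h = hw[["h"]], w = hw[["w"]]))
  }
  out <- sd_tensor(cpp_avgpool(x$v, as.integer(k), as.integer(stride), as.integer(pad)))
  if (tape_active()) {
    H <- dim(x$v)[2]; W <- dim(x$v)[3]
    push_node(out, function(g)
      add_grad(x, cpp_avgpool_bw(g, as.integer(k), as.integer(stride),
                                 as.integer(pad), H, W)))
  }
  out
}

#' Nearest-neighbour 2x upsampling
#' @param x input
#' @export
op_upsample2 <- function(x) {
  if (is_shape(x)) return(shape_like(x, h = 2L * x$dims[["H"]], w = 2L * x$dims[["W"]]))
  d <- dim(x$v)
  v <- x$v[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), , drop = FALSE]
  out <- sd_tensor(v)
  if (tape_active()) {
    push_node(out, function(g) {
      gg <- g[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
        g[, seq(2, 2 * d[2], 2), , , drop = FALSE]
      gx <- gg[, , seq(1, 2 * d[3], 2), , drop = FALSE] +
        gg[, , seq(2, 2 * d[3], 2), , drop = FALSE]
      add_grad(x, gx)
    })
  }
  out
}

#' Per-position mean over the channel axis (1 x H x W output)
#' @param x input
#' @export
op_channel_mean <- function(x) {
  if (is_shape(x)) return(shape_like(x, c = 1L))
  d <- dim(x$v)
  v <- array(colMeans(matrix(x$v, nrow = d[1])), c(1L, d[2], d[3], d[4]))
  out <- sd_tensor(v)
  if (tape_active()) {
    push_node(out, function(g)
      add_grad(x, array(rep(g / d[1], each = d[1]), d)))
  }
  out
}

#' Per-position max over the channel axis (1 x H x W output)
#' @param x input
#' @export
op_channel_max <- function(x) {
  if (is_shape(x)) return(shape_like(x, c = 1L))
  d <- dim(x$v)
  M <- matrix(x$v, nrow = d[1])
  wh <- max.col(t(M), ties.method = "first")
  v <- array(M[cbind(wh, seq_len(ncol(M)))], c(1L, d[2], d[3], d[4]))
  out <- sd_tensor(v)
  if (tape_active()) {
    push_node(out, function(g) {
      gx <- matrix(0, nrow = d[1], ncol = ncol(M))
      gx[cbind(wh, seq_len(ncol(M)))] <- as.vector(g)
      add_grad(x, array(gx, d))
    })
  }
  out
}

#' Stochastic depth (drop-path) on the residual branch
#'
#' During training each sample's branch output is zeroed with probability
#' `rate` and survivors are rescaled by 1/(1-rate); identity at rate 0 or in
#' inference mode.
#' @param x input; @param rate drop probability in [0, 1)
#' @export
op_droppath <- function(x, rate) {
  if (is_shape(x) || rate <= 0 || !is_training()) return(x)
  d <- dim(x$v)
  keep <- (stats::runif(d[4]) >= rate) / (1 - rate)
  km <- array(rep(keep, each = d[1] * d[2] * d[3]), d)
  out <- sd_tensor(x$v * km)
  if (tape_active()) push_node(out, function(g) add_grad(x, g * km))
  out
}

#' Multi-head self-attention over spatial positions
#'
#' Consumes a fused qkv tensor whose channels hold, per head, `key_dim` query
#' rows, `key_dim` key rows and `head_dim` value rows. Returns the attended
#' values with `num_heads * head_dim` channels.
#' @param qkv fused projection tensor
#' @param num_heads,key_dim,head_dim attention geometry
#' @export
op_mhsa <- function(qkv, num_heads, key_dim, head_dim) {
  blk <- 2L * key_dim + head_dim
  if (is_shape(qkv)) return(shape_like(qkv, c = num_heads * head_dim))
  d <- dim(qkv$v)
  N <- d[2] * d[3]
  sc <- key_dim^-0.5
  out_v <- array(0, c(num_heads * head_dim, d[2], d[3], d[4]))
  cache <- vector("list", d[4] * num_heads)
  X <- array(qkv$v, c(d[1], N, d[4]))
  for (b in seq_len(d[4])) {
    for (h in seq_len(num_heads)) {
      off <- (h - 1L) * blk
      q <- X[off + seq_len(key_dim), , b, drop = TRUE]
      k <- X[off + key_dim + seq_len(key_dim), , b, drop = TRUE]
      v <- X[off + 2L * key_dim + seq_len(head_dim), , b, drop = TRUE]
      q <- matrix(q, key_dim, N); k <- matrix(k, key_dim, N)
      v <- matrix(v, head_dim, N)
      a <- crossprod(q, k) * sc            # N x N, rows = query index
      a <- exp(a - apply(a, 1, max))
      a <- a / rowSums(a)
      o <- v %*% t(a)                      # head_dim x N
      out_v[(h - 1L) * head_dim + seq_len(head_dim), , , b] <-
        array(o, c(head_dim, d[2], d[3]))
      cache[[(b - 1L) * num_heads + h]] <- list(q = q, k = k, v = v, a = a)
    }
  }
  out <- sd_tensor(out_v)
  if (tape_active()) {
    push_node(out, function(g) {
      gq <- array(0, dim(qkv$v))
      G <- array(g, c(num_heads * head_dim, N, d[4]))
      for (b in seq_len(d[4])) {
        for (h in seq_len(num_heads)) {
          cc <- cache[[(b - 1L) * num_heads + h]]
          go <- matrix(G[(h - 1L) * head_dim + seq_len(head_dim), , b],
                       head_dim, N)
          ga <- t(crossprod(cc$v, go))                  # N x N (query rows)
          gs <- cc$a * (ga - rowSums(cc$a * ga))        # softmax backward
          gqm <- cc$k %*% t(gs) * sc                    # key_dim x N
          gkm <- cc$q %*% gs * sc
          gvm <- go %*% cc$a
          off <- (h - 1L) * blk
          idx <- function(rows, m) {
            gq[off + rows, , , b] <<- gq[off + rows, , , b] +
              array(m, c(length(rows), d[2], d[3]))
          }
          idx(seq_len(key_dim), gqm)
          idx(key_dim + seq_len(key_dim), gkm)
          idx(2L * key_dim + seq_len(head_dim), gvm)
        }
      }
      add_grad(qkv, gq)
    })
  }
  out
}

#' Gather the value channels out of a fused qkv tensor
#' @param qkv fused tensor; @param num_heads,key_dim,head_dim geometry
#' @export
op_gather_v <- function(qkv, num_heads, key_dim, head_dim) {
  blk <- 2L * key_dim + head_dim
  rows <- as.vector(vapply(seq_len(num_heads) - 1L,
                           function(h) as.integer(h * blk + 2L * key_dim +
                                                    seq_len(head_dim)),
                           integer(head_dim)))
  if (is_shape(qkv)) return(shape_like(qkv, c = num_heads * head_dim))
  out <- sd_tensor(qkv$v[rows, , , , drop = FALSE])
  if (tape_active()) {
    d <- dim(qkv$v)
    push_node(out, function(g) {
      gx <- array(0, d)
      gx[rows, , , ] <- g
      add_grad(qkv, gx)
    })
  }
  out
}
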