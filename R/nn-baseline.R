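# Baseline building blocks of the nano-scale single-stage detector that the
# bespoke modules replace: C3k2 / SPPF / C2PSA and the decoupled
# box-regression + classification head with distribution-focal-loss (DFL)
# box encoding.

#' Standard residual bottleneck (two convs + optional shortcut)
#' @param c_in,c_out channels; @param shortcut residual add when shapes match
#' @param k1,k2 kernel sizes; @param e hidden expansion
#' @export
nn_bottleneck <- function(c_in, c_out, shortcut = TRUE, k1 = 3L, k2 = 3L, e = 0.5) {
  ch <- as.integer(c_out * e)
  new_module("bottleneck", c_out = c_out,
             add = shortcut && c_in == c_out,
             .mods = list(cv1 = nn_conv(c_in, ch, k1),
                         cv2 = nn_conv(ch, c_out, k2)))
}

#' @export
fwd.sd_bottleneck <- function(m, x, ...) {
  y <- fwd(m$mods$cv2, fwd(m$mods$cv1, x))
  if (m$add) op_add(x, y) else y
}

#' CSP block with two inner full-kernel bottlenecks (the "heavy" C3k variant)
#' @param c_in,c_out channels; @param n inner bottleneck count
#' @export
nn_c3k <- function(c_in, c_out, n = 2L) {
  ch <- as.integer(c_out * 0.5)
  new_module("c3k", c_out = c_out, .mods = list(
    cv1 = nn_conv(c_in, ch, 1L),
    cv2 = nn_conv(c_in, ch, 1L),
    cv3 = nn_conv(2L * ch, c_out, 1L),
    m = nn_seq(lapply(seq_len(n), function(i)
      nn_bottleneck(ch, ch, shortcut = TRUE, k1 = 3L, k2 = 3L, e = 1.0)))
  ))
}

#' @export
fwd.sd_c3k <- function(m, x, ...) {
  a <- fwd(m$mods$m, fwd(m$mods$cv1, x))
  b <- fwd(m$mods$cv2, x)
  fwd(m$mods$cv3, op_concat(list(a, b)))
}

#' Split-transform-merge feature block (C3k2)
#'
#' The default feature-extraction unit of the baseline: a 1x1 conv expands to
#' two branches, `n` inner blocks refine one branch, and all intermediate maps
#' are concatenated and fused back to `c_out`.
#' @param c_in,c_out channels; @param n repeat count
#' @param c3k use the heavier C3k inner block instead of a bottleneck
#' @param e hidden width ratio; @param shortcut inner residuals
#' @export
nn_c3k2 <- function(c_in, c_out, n = 1L, c3k = FALSE, e = 0.5, shortcut = TRUE) {
  ch <- as.integer(c_out * e)
  inner <- lapply(seq_len(n), function(i) {
    if (c3k) nn_c3k(ch, ch, 2L) else nn_bottleneck(ch, ch, shortcut, 3L, 3L, 0.5)
  })
  new_module("c3k2", c_out = c_out, c_hidden = ch, n = n, .mods = c(list(
    cv1 = nn_conv(c_in, 2L * ch, 1L),
    cv2 = nn_conv((2L + n) * ch, c_out, 1L)
  ), stats::setNames(inner, paste0("m", seq_len(n)))))
}

#' @export
fwd.sd_c3k2 <- function(m, x, ...) {
  ch <- m$c_hidden
  y <- fwd(m$mods$cv1, x)
  ys <- list(op_slice_c(y, 1L, ch), op_slice_c(y, ch + 1L, 2L * ch))
  for (i in seq_len(m$n)) ys[[length(ys) + 1L]] <- fwd(m$mods[[paste0("m", i)]], ys[[length(ys)]])
  fwd(m$mods$cv2, op_concat(ys))
}

#' Spatial pyramid pooling (fast variant)
#' @param c_in,c_out channels; @param k pooling window
#' @export
nn_sppf <- function(c_in, c_out, k = 5L) {
  ch <- c_in %/% 2L
  new_module("sppf", c_out = c_out, k = k, .mods = list(
    cv1 = nn_conv(c_in, ch, 1L),
    cv2 = nn_conv(4L * ch, c_out, 1L)
  ))
}

#' @export
fwd.sd_sppf <- function(m, x, ...) {
  y <- fwd(m$mods$cv1, x)
  p1 <- op_maxpool(y, m$k, 1L, m$k %/% 2L)
  p2 <- op_maxpool(p1, m$k, 1L, m$k %/% 2L)
  p3 <- op_maxpool(p2, m$k, 1L, m$k %/% 2L)
  fwd(m$mods$cv2, op_concat(list(y, p1, p2, p3)))
}

#' Position-sensitive attention block stack (C2PSA)
#' @param c_in channels (output equals input); @param n block count
#' @export
nn_c2psa <- function(c_in, n = 1L) {
  ch <- c_in %/% 2L
  blocks <- lapply(seq_len(n), function(i) nn_psablock(ch))
  new_module("c2psa", c_out = c_in, c_hidden = ch, n = n, .mods = c(list(
    cv1 = nn_conv(c_in, 2L * ch, 1L),
    cv2 = nn_conv(2L * ch, c_in, 1L)
  ), stats::setNames(blocks, paste0("m", seq_len(n)))))
}

#' @export
fwd.sd_c2psa <- function(m, x, ...) {
  y <- fwd(m$mods$cv1, x)
  a <- op_slice_c(y, 1L, m$c_hidden)
  b <- op_slice_c(y, m$c_hidden + 1L, 2L * m$c_hidden)
  for (i in seq_len(m$n)) b <- fwd(m$mods[[paste0("m", i)]], b)
  fwd(m$mods$cv2, op_concat(list(a, b)))
}

#' Attention + feed-forward residual block used inside C2PSA
#' @param c channels
#' @export
nn_psablock <- function(c) {
  new_module("psablock", c_out = c, .mods = list(
    attn = nn_attention(c, num_heads = max(1L, c %/% 64L)),
    ffn1 = nn_conv(c, 2L * c, 1L),
    ffn2 = nn_conv(2L * c, c, 1L, act = "none")
  ))
}

#' @export
fwd.sd_psablock <- function(m, x, ...) {
  x <- op_add(x, fwd(m$mods$attn, x))
  op_add(x, fwd(m$mods$ffn2, fwd(m$mods$ffn1, x)))
}

#' Multi-head self-attention with positional depthwise conv
#' @param dim channels; @param num_heads heads; @param attn_ratio key width ratio
#' @export
nn_attention <- function(dim, num_heads, attn_ratio = 0.5) {
  head_dim <- dim %/% num_heads
  key_dim <- as.integer(head_dim * attn_ratio)
  h <- dim + 2L * key_dim * num_heads
  new_module("attention", c_out = dim, num_heads = num_heads,
             key_dim = key_dim, head_dim = head_dim, .mods = list(
    qkv = nn_conv(dim, h, 1L, act = "none"),
    proj = nn_conv(dim, dim, 1L, act = "none"),
    pe = nn_conv(dim, dim, 3L, g = dim, act = "none")
  ))
}

#' @export
fwd.sd_attention <- function(m, x, ...) {
  qkv <- fwd(m$mods$qkv, x)
  att <- op_mhsa(qkv, m$num_heads, m$key_dim, m$head_dim)
  v <- op_gather_v(qkv, m$num_heads, m$key_dim, m$head_dim)
  fwd(m$mods$proj, op_add(att, fwd(m$mods$pe, v)))
}

#' Baseline decoupled detection head
#'
#' Per level: a two-conv box branch emitting `4 * reg_max` DFL logits and a
#' depthwise-separable classification branch emitting `nc` logits. Each level
#' has its own weights (the parameter redundancy the shared head removes).
#' @param nc classes; @param ch input channels per level; @param reg_max DFL bins
#' @export
nn_detect <- function(nc, ch, reg_max = 16L) {
  c2 <- max(16L, ch[1] %/% 4L, reg_max * 4L)
  c3 <- max(ch[1], min(nc, 100L))
  lv <- function(i) {
    x <- ch[i]
    list(
      box = nn_seq(list(nn_conv(x, c2, 3L), nn_conv(c2, c2, 3L),
                        nn_conv(c2, 4L * reg_max, 1L, act = "none", norm = "none",
                                bias = TRUE))),
      cls = nn_seq(list(
        nn_conv(x, x, 3L, g = gcd_int(x, x)), nn_conv(x, c3, 1L),
        nn_conv(c3, c3, 3L, g = c3), nn_conv(c3, c3, 1L),
        nn_conv(c3, nc, 1L, act = "none", norm = "none", bias = TRUE)))
    )
  }
  mods <- list()
  for (i in seq_along(ch)) {
    l <- lv(i)
    mods[[paste0("box", i)]] <- l$box
    mods[[paste0("cls", i)]] <- l$cls
  }
  new_module("detect", c_out = NA_integer_, nc = nc, nl = length(ch),
             reg_max = reg_max, .mods = mods)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' @export
fwd.sd_detect <- function(m, x, ...) {
  # x: list of level tensors; returns per-level raw predictions
  lapply(seq_len(m$nl), function(i) list(
    box = fwd(m$mods[[paste0("box", i)]], x[[i]]),
    cls = fwd(m$mods[[paste0("cls", i)]], x[[i]])
  ))
}
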