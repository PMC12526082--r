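# The four bespoke network modules: the mixed-aggregation feature-enhancement
# block with spatial attention (backbone unit), the adaptive downsampler, the
# group-normalized shared detection head, and DFL box decoding.

#' Block configuration
#'
#' Bundles the tunable hyper-parameters of the bespoke blocks.
#'
#' @param out_channels output channel count (even where a block emits 2c)
#' @param n_repeats chain length of partial-conv blocks in the
#'   mixed-aggregation unit
#' @param partial_ratio fraction of channels entering the 3x3 partial conv
#' @param expansion pointwise expansion ratio inside a partial-conv block
#' @param droppath_rate stochastic-depth drop probability
#' @param reg_max number of discrete DFL bins per box side
#' @param hidden_channels shared-head width (`hidc`); NULL = smallest input level
#' @param gn_eps group-norm variance floor
#' @return a `block_config` list
#' @export
block_config <- function(out_channels = 64L, n_repeats = 1L, partial_ratio = 0.25,
                         expansion = 2L, droppath_rate = 0, reg_max = 16L,
                         hidden_channels = NULL, gn_eps = 1e-5,
                         hidden_ratio = 0.5, x2_ratio = 2L) {
  stopifnot(out_channels >= 1L, n_repeats >= 1L,
            partial_ratio > 0, partial_ratio <= 1,
            droppath_rate >= 0, droppath_rate < 1, reg_max >= 2L,
            hidden_ratio > 0, hidden_ratio <= 1, x2_ratio %in% c(1L, 2L))
  structure(list(out_channels = as.integer(out_channels),
                 n_repeats = as.integer(n_repeats),
                 partial_ratio = partial_ratio, expansion = expansion,
                 droppath_rate = droppath_rate, reg_max = as.integer(reg_max),
                 hidden_channels = hidden_channels, gn_eps = gn_eps,
                 hidden_ratio = hidden_ratio, x2_ratio = as.integer(x2_ratio)),
            class = "block_config")
}

#' Partial-convolution residual block
#'
#' A 3x3 convolution over the first `ceil(partial_ratio * C)` channels (the
#' rest pass through untouched), two pointwise convs with expansion, and a
#' residual add under stochastic depth: `Y = X + DropPath(W2 * silu(W1 * Z))`.
#' @param c channels (in = out); @param partial_ratio,expansion,droppath see
#'   [block_config()]
#' @export
nn_faster_block <- function(c, partial_ratio = 0.25, expansion = 2L, droppath = 0) {
  if (partial_ratio * c < 1)
    stop("faster block: partial channel slice is empty (partial_ratio * C < 1)")
  pc <- as.integer(ceiling(partial_ratio * c))
  ce <- as.integer(c * expansion)
  new_module("faster_block", c_out = c, pc = pc, droppath = droppath, .mods = list(
    pconv = nn_conv(pc, pc, 3L, act = "none", norm = "none", bias = FALSE),
    cv1 = nn_conv(c, ce, 1L),
    cv2 = nn_conv(ce, c, 1L, act = "none", norm = "none", bias = FALSE)
  ))
}

#' @export
fwd.sd_faster_block <- function(m, x, ...) {
  cc <- if (is_shape(x)) x$dims[["C"]] else dim(x$v)[1]
  zp <- fwd(m$mods$pconv, op_slice_c(x, 1L, m$pc))
  z <- if (m$pc < cc) op_concat(list(zp, op_slice_c(x, m$pc + 1L, cc))) else zp
  u <- fwd(m$mods$cv2, fwd(m$mods$cv1, z))
  op_add(x, op_droppath(u, m$droppath))
}

#' Spatial attention by channel pooling
#'
#' Mean and max maps over the channel axis (each 1 x H x W) are concatenated,
#' passed through a single 7x7 convolution and a sigmoid, and the resulting
#' weight map in (0,1) rescales every channel of the input.
#' @param k attention conv kernel
#' @export
nn_ema_attention <- function(k = 7L) {
  new_module("ema", c_out = NA_integer_, .mods = list(
    cv = nn_conv(2L, 1L, k, act = "none", norm = "none", bias = TRUE)
  ))
}

#' @export
fwd.sd_ema <- function(m, x, ...) {
  w <- op_sigmoid(fwd(m$mods$cv, op_concat(list(op_channel_mean(x),
                                                op_channel_max(x)))))
  op_mul_spatial(x, w)
}

#' Mixed-aggregation feature-enhancement block
#'
#' Three parallel feature paths over a shared stem (1x1 conv to 2c channels):
#' channel compression (1x1 to c), spatial modelling (1x1 then depthwise-
#' separable 3x3, keeping 2c), and a channel split into two c-wide halves with
#' `n` chained partial-conv residual blocks; all `(5+n)c` channels are
#' concatenated, fused by a 1x1 conv to `out_channels`, and recalibrated by
#' the channel-pooling spatial attention.
#' @param c_in input channels; @param cfg a [block_config()]
#' @export
nn_mixed_aggregation <- function(c_in, cfg) {
  c2 <- cfg$out_channels
  if (c2 %% 2L != 0L) stop("mixed aggregation block: out_channels must be even (2c)")
  # hidden width c; at the default hidden_ratio = 0.5 the stem emits 2c = c2
  # and the block output is exactly "2c channels"
  c <- max(2L, as.integer(round(c2 * cfg$hidden_ratio)))
  n <- cfg$n_repeats
  x2 <- cfg$x2_ratio
  fbs <- lapply(seq_len(n), function(i)
    nn_faster_block(c, cfg$partial_ratio, cfg$expansion, cfg$droppath_rate))
  new_module("femanet", c_out = c2, c = c, n = n, .mods = c(list(
    cv_first = nn_conv(c_in, 2L * c, 1L),
    cv_a = nn_conv(2L * c, c, 1L),
    cv_b_pre = nn_conv(2L * c, 2L * c, 1L),
    cv_b_ds = nn_dsconv(2L * c, x2 * c, 3L),
    cv_final = nn_conv((3L + x2 + n) * c, c2, 1L),
    ema = nn_ema_attention()
  ), stats::setNames(fbs, paste0("fb", seq_len(n)))))
}

#' @export
fwd.sd_femanet <- function(m, x, ...) {
  c <- m$c
  xmid <- fwd(m$mods$cv_first, x)
  paths <- list(
    fwd(m$mods$cv_a, xmid),
    fwd(m$mods$cv_b_ds, fwd(m$mods$cv_b_pre, xmid)),
    op_slice_c(xmid, 1L, c),
    op_slice_c(xmid, c + 1L, 2L * c)
  )
  for (i in seq_len(m$n))
    paths[[length(paths) + 1L]] <- fwd(m$mods[[paste0("fb", i)]], paths[[length(paths)]])
  fwd(m$mods$ema, fwd(m$mods$cv_final, op_concat(paths)))
}

#' Adaptive downsampling block
#'
#' A k=2 s=1 average pool, a channel split into halves, a stride-2 3x3 conv on
#' one half and a 3x3/s2 max pool + 1x1 conv on the other, concatenated to
#' `out_channels` at half resolution.
#' @param c_in input channels (must be even); @param c_out output channels (2C')
#' @export
nn_adown <- function(c_in, c_out) {
  if (c_in %% 2L != 0L) stop("adown: input channel count must be even")
  if (c_out %% 2L != 0L) stop("adown: output channel count must be even")
  ch <- c_in %/% 2L
  cp <- c_out %/% 2L
  new_module("adown", c_out = c_out, c_half = ch, .mods = list(
    cv1 = nn_conv(ch, cp, 3L, s = 2L, p = 1L),
    cv2 = nn_conv(ch, cp, 1L)
  ))
}

#' @export
fwd.sd_adown <- function(m, x, ...) {
  xp <- op_avgpool(x, 2L, 1L, 0L)
  x1 <- op_slice_c(xp, 1L, m$c_half)
  x2 <- op_slice_c(xp, m$c_half + 1L, 2L * m$c_half)
  op_concat(list(fwd(m$mods$cv1, x1),
                 fwd(m$mods$cv2, op_maxpool(x2, 3L, 2L, 1L))))
}

#' Group-normalized shared detection head
#'
#' Each level first passes an independent 3x3 conv (+ group norm) to `hidc`
#' channels; a single shared depthwise-separable stage (3x3 grouped conv with
#' groups = hidc, then 1x1, each group-normalized) and shared 1x1 prediction
#' convs then serve every level, with one learnable scalar per level
#' modulating the box output. Weight storage is shared: the shared convs
#' contribute parameters once regardless of level count.
#' @param nc classes; @param ch input channels per level
#' @param hidc shared width (default: smallest input level)
#' @param reg_max DFL bins
#' @export
nn_gscd_head <- function(nc, ch, hidc = NULL, reg_max = 16L) {
  hidc <- as.integer(hidc %||% min(ch))
  ins <- lapply(ch, function(x) nn_conv(x, hidc, 3L, norm = "gn"))
  scales <- lapply(ch, function(x) nn_scale(1))
  new_module("gscd", c_out = NA_integer_, nc = nc, nl = length(ch),
             reg_max = reg_max, hidc = hidc, .mods = c(
    stats::setNames(ins, paste0("in", seq_along(ch))),
    list(share_dw = nn_conv(hidc, hidc, 3L, g = hidc, norm = "gn"),
         share_pw = nn_conv(hidc, hidc, 1L, norm = "gn"),
         cv2 = nn_conv(hidc, 4L * reg_max, 1L, act = "none", norm = "none",
                       bias = TRUE),
         cv3 = nn_conv(hidc, nc, 1L, act = "none", norm = "none", bias = TRUE)),
    stats::setNames(scales, paste0("scale", seq_along(ch)))
  ))
}

#' @export
fwd.sd_gscd <- function(m, x, ...) {
  lapply(seq_len(m$nl), function(i) {
    s <- fwd(m$mods$share_pw,
             fwd(m$mods$share_dw, fwd(m$mods[[paste0("in", i)]], x[[i]])))
    list(box = fwd(m$mods[[paste0("scale", i)]], fwd(m$mods$cv2, s)),
         cls = fwd(m$mods$cv3, s))
  })
}

# ---- functional surfaces ----------------------------------------------------

as_input <- function(x) {
  if (inherits(x, "sd_tensor") || is_shape(x)) x else sd_tensor(x)
}

#' Apply a partial-convolution residual block
#' @param x 4-D array or tensor (C,H,W,B); @param cfg a [block_config()]
#' @param module optional pre-built module (weights reused across calls)
#' @return tensor with the input's shape
#' @export
faster_block <- function(x, cfg = block_config(), module = NULL) {
  x <- as_input(x)
  c <- if (is_shape(x)) x$dims[["C"]] else dim(x$v)[1]
  if (ceiling(cfg$partial_ratio * c) < 1L)
    stop("faster_block: partial channel slice is empty")
  m <- module %||% nn_faster_block(c, cfg$partial_ratio, cfg$expansion,
                                   cfg$droppath_rate)
  fwd(m, x)
}

#' Apply channel-pooling spatial attention
#' @inheritParams faster_block
#' @export
ema_attention <- function(x, module = NULL) {
  x <- as_input(x)
  fwd(module %||% nn_ema_attention(), x)
}

#' Apply the mixed-aggregation feature-enhancement block
#' @inheritParams faster_block
#' @export
femanet <- function(x, cfg = block_config(), module = NULL) {
  x <- as_input(x)
  c_in <- if (is_shape(x)) x$dims[["C"]] else dim(x$v)[1]
  fwd(module %||% nn_mixed_aggregation(c_in, cfg), x)
}

#' Apply adaptive downsampling
#' @inheritParams faster_block
#' @export
adown <- function(x, cfg = block_config(), module = NULL) {
  x <- as_input(x)
  c_in <- if (is_shape(x)) x$dims[["C"]] else dim(x$v)[1]
  fwd(module %||% nn_adown(c_in, cfg$out_channels), x)
}

#' Group normalization of a feature map
#'
#' Standardizes each channel group within each sample and applies an affine
#' transform; with `groups` equal to the channel count this is per-channel
#' normalization.
#' @param x 4-D array or tensor (C,H,W,B)
#' @param groups channel groups (default: the channel count)
#' @param gamma,beta per-channel affine vectors (defaults 1 and 0)
#' @param eps variance floor
#' @return array with the input's shape
#' @export
group_norm <- function(x, groups = NULL, gamma = NULL, beta = NULL, eps = 1e-5) {
  x <- as_input(x)
  C <- if (is_shape(x)) x$dims[["C"]] else dim(x$v)[1]
  groups <- as.integer(groups %||% C)
  g <- sd_tensor(array(rep_len(gamma %||% 1, C), c(C, 1, 1, 1)))
  b <- sd_tensor(array(rep_len(beta %||% 0, C), c(C, 1, 1, 1)))
  out <- op_gn(x, g, b, groups, eps)
  if (is_shape(out)) out else out$v
}

#' Decode distribution-focal-loss logits to distances
#'
#' Each box side is a categorical distribution over `reg_max` bins; the
#' decoded distance is its expectation, `sum_d softmax(logits)_d * d`, hence
#' always inside [0, reg_max - 1].
#'
#' @param logits a matrix with `reg_max` rows (one column per side-location),
#'   or a 4-D array whose channel dim is a multiple of `reg_max`
#' @param reg_max number of bins
#' @return expectations: a vector (matrix input) or 4-D array with
#'   `channels / reg_max` channels
#' @export
dfl_decode <- function(logits, reg_max = 16L) {
  expect <- function(M) {
    M <- exp(sweep(M, 2, apply(M, 2, max)))
    M <- sweep(M, 2, colSums(M), `/`)
    as.vector(crossprod(M, 0:(nrow(M) - 1L)))
  }
  if (is.matrix(logits)) {
    stopifnot(nrow(logits) == reg_max)
    return(expect(logits))
  }
  v <- if (inherits(logits, "sd_tensor")) logits$v else logits
  d <- dim(v)
  stopifnot(d[1] %% reg_max == 0L)
  sides <- d[1] %/% reg_max
  M <- matrix(v, nrow = reg_max)  # bins fastest within channel dim
  array(expect(M), c(sides, d[2], d[3], d[4]))
}

#' Apply the shared detection head to a list of feature maps
#'
#' Training mode returns one raw prediction set per level; inference mode
#' additionally sigmoid-activates class logits.
#' @param features list of tensors/arrays, one per level
#' @param num_classes class count; @param cfg a [block_config()]
#' @param module optional pre-built head
#' @param mode "train" or "inference"
#' @export
gscdhead <- function(features, num_classes = 1L, cfg = block_config(),
                     module = NULL, mode = c("train", "inference")) {
  mode <- match.arg(mode)
  features <- lapply(features, as_input)
  ch <- vapply(features, function(x)
    if (is_shape(x)) x$dims[["C"]] else dim(x$v)[1], integer(1))
  m <- module %||% nn_gscd_head(num_classes, ch, cfg$hidden_channels, cfg$reg_max)
  out <- fwd(m, features)
  if (mode == "inference" && !is_shape(features[[1]]))
    out <- lapply(out, function(l) list(box = l$box, cls = op_sigmoid(l$cls)))
  out
}

# Zero every parameter of a module tree (testing aid: residual identities).
zero_params <- function(m) {
  for (p in collect_params(m)) p$v[] <- 0
  invisible(m)
}
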