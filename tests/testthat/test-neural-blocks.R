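# The four bespoke blocks, tested in isolation against their defining
# behaviour: residual identities, shape contracts, channel bookkeeping,
# attention ranges, DFL expectations, and the shared-weight head.

test_that("partial-conv residual block: identity at zero weights, shape preserved", {
  set.seed(201)
  x <- rand_t(64, 8, 8, 1)
  m <- nn_faster_block(64, partial_ratio = 0.25, expansion = 2L, droppath = 0)
  spikedet:::zero_params(m)
  expect_equal(fwd(m, x)$v, x$v)
  # chaining zero blocks stays the identity (residual cascade)
  expect_equal(fwd(m, fwd(m, x))$v, x$v)
  m2 <- nn_faster_block(64)
  expect_equal(dim(fwd(m2, x)$v), c(64L, 8L, 8L, 1L))
})

test_that("partial-conv block: slice width and hand-summed weight count", {
  m <- nn_faster_block(64, partial_ratio = 0.25, expansion = 2L)
  expect_equal(m$pc, 16L)  # exactly 16 of 64 channels enter the 3x3 conv
  kernel_numel <- sum(vapply(spikedet:::collect_params(m), function(p) {
    d <- dim(p$v)
    if (d[2] > 0 && prod(d[2:3]) >= 1 && length(p$v) > d[1]) length(p$v) else 0
  }, numeric(1)))
  # oracle: 16*16*9 (partial 3x3) + 64*(64*2) (expand 1x1) + (64*2)*64 (project)
  e <- 2
  expect_equal(kernel_numel, 16 * 16 * 9 + 64 * 64 * e + 64 * e * 64)
  expect_error(faster_block(array(rnorm(2 * 4 * 4), c(2, 4, 4, 1)),
                            block_config(partial_ratio = 1e-9)),
               "partial channel")
})

test_that("spatial attention: weights in (0,1), constant input gives constant map", {
  set.seed(202)
  m <- nn_ema_attention()
  x <- rand_t(32, 20, 20, 2)
  out <- ema_attention(x, module = m)
  w <- out$v / x$v
  expect_true(all(w > 0 & w < 1))
  expect_equal(dim(out$v), dim(x$v))
  # constant input: the pooled mean and max maps coincide and are spatially
  # constant, so away from the zero-padded border the attention weight is one
  # constant and the output is constant * x
  xc <- sd_tensor(array(2.5, c(4, 16, 16, 1)))
  expect_equal(op_channel_mean(xc)$v[1, , , 1], op_channel_max(xc)$v[1, , , 1])
  oc <- ema_attention(xc, module = m)
  interior <- oc$v[, 5:12, 5:12, 1] / xc$v[, 5:12, 5:12, 1]
  expect_lt(diff(range(interior)), 1e-12)
  # brute-force pooling oracle on a channel-varying tensor
  xv <- sd_tensor(array(rep(1:4, 9), c(4, 3, 3, 1)))
  expect_equal(as.vector(op_channel_mean(xv)$v), rep(mean(1:4), 9))
  expect_equal(as.vector(op_channel_max(xv)$v), rep(4, 9))
})

test_that("mixed-aggregation block: 2c output, concat bookkeeping, residual chain", {
  set.seed(203)
  x <- rand_t(64, 16, 16, 1)
  m <- nn_mixed_aggregation(64L, block_config(out_channels = 64L, n_repeats = 1L))
  expect_equal(dim(fwd(m, x)$v), c(64L, 16L, 16L, 1L))
  # concatenation width before the fusion conv is (5+n)*c for the default
  # 2c-wide spatial path
  for (n in 1:3) {
    mm <- nn_mixed_aggregation(64L, block_config(out_channels = 64L,
                                                 n_repeats = n))
    expect_equal(mm$mods$cv_final$c_in, (5L + n) * 32L)
  }
  expect_error(nn_mixed_aggregation(64L, block_config(out_channels = 63L)),
               "even")
  # residual cascade: zero partial-block weights make every chain element
  # equal its input
  m3 <- nn_mixed_aggregation(64L, block_config(out_channels = 64L,
                                               n_repeats = 2L))
  spikedet:::zero_params(m3$mods$fb1)
  spikedet:::zero_params(m3$mods$fb2)
  xm <- fwd(m3$mods$cv_first, x)
  x4 <- op_slice_c(xm, 33L, 64L)
  expect_equal(fwd(m3$mods$fb2, fwd(m3$mods$fb1, x4))$v, x4$v)
})

test_that("adaptive downsampling: halving contract and channel checks", {
  set.seed(204)
  x <- rand_t(32, 64, 64, 1)
  m <- nn_adown(32L, 32L)
  out <- fwd(m, x)
  expect_equal(dim(out$v), c(32L, 32L, 32L, 1L))
  expect_error(nn_adown(31L, 32L), "even")
  # shape probe route agrees
  s <- fwd(m, sd_shape(32, 64, 64))
  expect_equal(unname(s$dims), c(32L, 32L, 32L, 1L))
})

test_that("group_norm: standardization, affine transform, divisibility", {
  x <- array(c(1, 3), c(1, 2, 1, 1))
  expect_equal(as.vector(group_norm(x, eps = 1e-12)), c(-1, 1),
               tolerance = 1e-5)
  expect_equal(as.vector(group_norm(x, gamma = 2, beta = 1, eps = 1e-12)),
               c(-1, 3), tolerance = 1e-5)
  bad <- array(rnorm(6 * 4), c(6, 2, 2, 1))
  expect_error(group_norm(bad, groups = 4), "divide")
})

test_that("DFL decode is the categorical expectation", {
  # near-one-hot mass at bin 7 (0-based)
  l <- matrix(-30, 16, 1); l[8, 1] <- 30
  expect_equal(dfl_decode(l, 16L), 7, tolerance = 1e-6)
  # uniform logits -> midpoint
  expect_equal(dfl_decode(matrix(0, 16, 1), 16L), 7.5)
  # 2 bins with logits (0, ln 3) -> 0.75
  expect_equal(dfl_decode(matrix(c(0, log(3)), 2, 1), 2L), 0.75)
  # bounded and monotone under mass shift toward higher bins
  set.seed(205)
  for (i in 1:20) {
    z <- matrix(rnorm(16), 16, 1)
    v <- dfl_decode(z, 16L)
    expect_true(v >= 0 && v <= 15)
    z2 <- z; z2[16, 1] <- z2[16, 1] + 1
    expect_gt(dfl_decode(z2, 16L), v)
  }
  # 4-side tensor route
  arr <- array(0, c(64, 2, 2, 1))
  expect_equal(dim(dfl_decode(arr, 16L)), c(4L, 2L, 2L, 1L))
  expect_true(all(dfl_decode(arr, 16L) == 7.5))
})

test_that("shared detection head: channel contract, per-level returns, sharing", {
  set.seed(206)
  feats <- list(rand_t(64, 8, 8, 1), rand_t(96, 4, 4, 1), rand_t(96, 4, 4, 1))
  head <- nn_gscd_head(1L, c(64L, 96L, 96L), hidc = 64L, reg_max = 16L)
  out <- fwd(head, feats)
  expect_length(out, 3L)                       # one prediction set per level
  expect_equal(dim(out[[1]]$box$v)[1], 64L)    # 4 * reg_max channels
  expect_equal(dim(out[[2]]$cls$v)[1], 1L)
  # scale init 1.0 -> modulation is the identity
  expect_equal(head$mods$scale1$params$s$v[1], 1)
  s_out <- fwd(head$mods$cv2, fwd(head$mods$share_pw,
               fwd(head$mods$share_dw, fwd(head$mods$in1, feats[[1]]))))
  expect_equal(out[[1]]$box$v, s_out$v)
  # the shared convs are one storage: perturbing them changes every level
  head$mods$share_dw$params$w$v[] <- head$mods$share_dw$params$w$v + 0.5
  out2 <- fwd(head, feats)
  for (i in 1:3) expect_false(isTRUE(all.equal(out[[i]]$box$v, out2[[i]]$box$v)))
  # shared parameters are counted once: three levels vs two levels differ only
  # by one per-level input conv + scale
  h2 <- nn_gscd_head(1L, c(64L, 96L), hidc = 64L)
  d <- count_parameters(head) - count_parameters(h2)
  expect_equal(d, count_parameters(nn_conv(96L, 64L, 3L, norm = "gn")) + 1L)
})

test_that("blocks preserve batch size and honour declared contracts on random probes", {
  set.seed(207)
  for (i in 1:50) {
    c_in <- sample(c(8L, 16L, 32L), 1)
    h <- sample(4:24, 1) * 2L
    w <- sample(4:24, 1) * 2L
    b <- sample(1:3, 1)
    probe <- sd_shape(c_in, h, w, b)
    blk <- sample(c("fb", "fem", "adown", "ema"), 1)
    out <- switch(blk,
      fb = fwd(nn_faster_block(c_in), probe),
      fem = fwd(nn_mixed_aggregation(c_in, block_config(out_channels = 2L * c_in)),
                probe),
      adown = fwd(nn_adown(c_in, c_in), probe),
      ema = fwd(nn_ema_attention(), probe))
    expect_equal(out$dims[["B"]], b)
    if (blk == "fb" || blk == "ema") expect_equal(out$dims[["C"]], c_in)
    if (blk == "fem") {
      expect_equal(out$dims[["C"]], 2L * c_in)
      expect_equal(out$dims[["H"]], h)
    }
    if (blk == "adown") {
      expect_equal(out$dims[["C"]], c_in)
      expect_equal(out$dims[["H"]], h %/% 2L)
      expect_equal(out$dims[["W"]], w %/% 2L)
    }
  }
})

test_that("finite inputs stay finite through the bespoke blocks", {
  set.seed(208)
  x <- rand_t(16, 12, 12, 2)
  for (m in list(nn_faster_block(16L),
                 nn_mixed_aggregation(16L, block_config(out_channels = 32L)),
                 nn_adown(16L, 16L), nn_ema_attention())) {
    expect_true(all(is.finite(fwd(m, x)$v)))
  }
})
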