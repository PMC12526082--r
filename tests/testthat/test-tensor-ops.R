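# The tensor layer against naive oracles and finite differences.

test_that("convolution matches a direct-loop oracle (plain, grouped, depthwise)", {
  set.seed(101)
  cases <- list(
    list(C = 5, Co = 4, k = 3, s = 1, p = 1, g = 1),
    list(C = 6, Co = 4, k = 3, s = 2, p = 1, g = 2),
    list(C = 4, Co = 4, k = 3, s = 1, p = 1, g = 4),
    list(C = 3, Co = 7, k = 1, s = 1, p = 0, g = 1)
  )
  for (cs in cases) {
    x <- array(rnorm(cs$C * 9 * 8 * 2), c(cs$C, 9, 8, 2))
    w <- array(rnorm(cs$C / cs$g * cs$k^2 * cs$Co),
               c(cs$C / cs$g, cs$k, cs$k, cs$Co))
    got <- op_conv2d(sd_tensor(x), sd_tensor(w), stride = cs$s, pad = cs$p,
                     groups = cs$g)$v
    expect_equal(got, naive_conv2d(x, w, cs$s, cs$p, cs$g), tolerance = 1e-10)
  }
})

test_that("average pooling k=2 s=1 matches a hand-computed sliding-window mean", {
  # integer ramp on a 2-channel 5x5 plane
  x <- array(0, c(2, 5, 5, 1))
  x[1, , , 1] <- matrix(1:25, 5, 5)
  x[2, , , 1] <- matrix(25:1, 5, 5)
  out <- op_avgpool(sd_tensor(x), 2L, 1L, 0L)$v
  expect_equal(dim(out), c(2L, 4L, 4L, 1L))
  expect_equal(out[1, , , 1], naive_avgpool_plane(matrix(1:25, 5, 5), 2, 1))
  expect_equal(out[2, , , 1], naive_avgpool_plane(matrix(25:1, 5, 5), 2, 1))
})

test_that("max pooling of a constant input is constant and k3 s2 halves dims", {
  x <- array(3.5, c(4, 8, 8, 1))
  out <- op_maxpool(sd_tensor(x), 3L, 2L, 1L)$v
  expect_equal(dim(out), c(4L, 4L, 4L, 1L))
  expect_true(all(out == 3.5))
  avg <- op_avgpool(sd_tensor(x), 2L, 1L, 0L)$v
  expect_true(all(abs(avg - 3.5) < 1e-12))
})

test_that("group normalization matches a brute-force oracle", {
  set.seed(102)
  x <- array(rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
  gamma <- runif(4, 0.5, 2); beta <- rnorm(4)
  for (groups in c(1, 2, 4)) {
    got <- group_norm(x, groups = groups, gamma = gamma, beta = beta)
    expect_equal(got, naive_group_norm(x, groups, gamma, beta),
                 tolerance = 1e-5)
  }
})

test_that("reverse-mode gradients agree with finite differences", {
  set.seed(103)
  old <- spikedet:::set_training(TRUE)
  on.exit(spikedet:::set_training(old))
  x <- rand_t(4, 8, 8, 2)
  blocks <- list(
    conv_bn_silu = nn_conv(4, 6, 3),
    conv_gn = nn_conv(4, 6, 3, norm = "gn"),
    dw_conv = nn_conv(4, 4, 3, g = 4L),
    strided = nn_conv(4, 8, 3, s = 2L)
  )
  for (nm in names(blocks)) {
    m <- blocks[[nm]]
    err <- gradcheck(function() fwd(m, x), c(list(x), spikedet:::collect_params(m)))
    expect_lt(err, 1e-5)
  }
  # pooling / upsampling / attention paths
  err <- gradcheck(function() op_maxpool(op_upsample2(x), 3L, 2L, 1L), list(x))
  expect_lt(err, 1e-5)
  at <- spikedet:::nn_attention(16L, 2L)
  xa <- rand_t(16, 4, 4, 2)
  err <- gradcheck(function() fwd(at, xa),
                   c(list(xa), spikedet:::collect_params(at)))
  expect_lt(err, 1e-5)
})

test_that("channel pooling ops reduce to one channel and backprop mass", {
  set.seed(104)
  x <- rand_t(6, 5, 4, 2)
  mn <- op_channel_mean(x); mx <- op_channel_max(x)
  expect_equal(dim(mn$v), c(1L, 5L, 4L, 2L))
  expect_equal(as.vector(mn$v[1, 2, 2, ]), colMeans(matrix(x$v[, 2, 2, ], 6)))
  expect_equal(as.vector(mx$v[1, 3, 1, ]), apply(matrix(x$v[, 3, 1, ], 6), 2, max))
  err <- gradcheck(function() op_channel_max(x), list(x))
  expect_lt(err, 1e-5)
})

test_that("shape probes trace shapes without arithmetic", {
  tr <- new_tracer()
  s <- sd_shape(3, 64, 64, 2, tracer = tr)
  m <- nn_conv(3, 8, 3, s = 2L)
  out <- fwd(m, s)
  expect_equal(unname(out$dims), c(8L, 32L, 32L, 2L))
  expect_equal(tr$macs, 3 * 9 * 8 * 32 * 32 * 2)
})
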