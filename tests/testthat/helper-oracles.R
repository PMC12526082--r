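# Shared test oracles: deliberately naive re-implementations, independent of
# the package's kernels.

# Direct-loop 2-D convolution (grouped), layout (C, H, W, B) / (Cg, k, k, Co).
naive_conv2d <- function(x, w, s = 1, p = 0, g = 1) {
  dx <- dim(x); dw <- dim(w)
  C <- dx[1]; H <- dx[2]; W <- dx[3]; B <- dx[4]
  Cg <- dw[1]; k <- dw[2]; Co <- dw[4]; Cog <- Co / g
  Ho <- (H + 2 * p - k) %/% s + 1
  Wo <- (W + 2 * p - k) %/% s + 1
  out <- array(0, c(Co, Ho, Wo, B))
  for (b in seq_len(B)) for (co in seq_len(Co)) {
    gi <- ceiling(co / Cog)
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(Cg)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        hi <- (ho - 1) * s - p + ki
        wi <- (wo - 1) * s - p + kj
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc <- acc + x[(gi - 1) * Cg + ci, hi, wi, b] * w[ci, ki, kj, co]
      }
      out[co, ho, wo, b] <- acc
    }
  }
  out
}

# Sliding-window mean over one (H, W) plane.
naive_avgpool_plane <- function(m, k, s) {
  H <- nrow(m); W <- ncol(m)
  Ho <- (H - k) %/% s + 1; Wo <- (W - k) %/% s + 1
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo))
    out[i, j] <- mean(m[(i - 1) * s + 1:k, (j - 1) * s + 1:k])
  out
}

# Brute-force group normalization, layout (C, H, W, B).
naive_group_norm <- function(x, groups, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  cg <- d[1] / groups
  out <- array(0, d)
  for (b in seq_len(d[4])) for (g in seq_len(groups)) {
    ch <- (g - 1) * cg + seq_len(cg)
    v <- x[ch, , , b]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    out[ch, , , b] <- (x[ch, , , b] - mu) / sqrt(va + eps)
  }
  sweep(sweep(out, 1, gamma, `*`), 1, beta, `+`)
}

# Finite-difference gradient check: returns the worst relative error over a
# random subset of entries of each tensor.
gradcheck <- function(f, tensors, n_probe = 6, eps = 1e-5) {
  out <- with_tape(f())
  gseed <- array(stats::rnorm(length(out$v)), dim(out$v))
  sd_backward(list(list(t = out, g = gseed)))
  worst <- 0
  for (t in tensors) {
    idx <- sample(length(t$v), min(n_probe, length(t$v)))
    for (i in idx) {
      v0 <- t$v[i]
      t$v[i] <- v0 + eps; f1 <- sum(f()$v * gseed)
      t$v[i] <- v0 - eps; f2 <- sum(f()$v * gseed)
      t$v[i] <- v0
      num <- (f1 - f2) / (2 * eps)
      worst <- max(worst, abs(num - t$grad[i]) / max(1, abs(num)))
    }
    t$grad <- NULL
  }
  worst
}

rand_t <- function(c, h, w, b = 1) {
  sd_tensor(array(stats::rnorm(c * h * w * b), c(c, h, w, b)))
}

# A small easy-scene dataset for fast training tests.
easy_imgs <- function(n, seed = 1, side = 320) {
  lapply(seq_len(n), function(i)
    generate_synthetic_field(width = side, height = side, seed = seed + i,
                             style = "easy"))
}
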