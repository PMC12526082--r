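# Module containers: every module is a classed list with
#   $params - named list of sd_tensor parameters owned directly
#   $mods   - named list of child modules
#   $c_out  - declared output channel count
# fwd() runs the module on an sd_tensor (numeric) or sd_shape (trace) input.

new_module <- function(.kind, ..., .params = list(), .mods = list()) {
  structure(c(list(kind = .kind, params = .params, mods = .mods), list(...)),
            class = c(paste0("sd_", .kind), "sd_module"))
}

#' Run a module forward
#' @param m module; @param x input tensor or shape probe; @param ... unused
#' @export
fwd <- function(m, x, ...) UseMethod("fwd")

kaiming <- function(c_in_g, kh, kw, c_out) {
  sd <- sqrt(2 / (c_in_g * kh * kw))
  array(stats::rnorm(c_in_g * kh * kw * c_out, sd = sd), c(c_in_g, kh, kw, c_out))
}

#' Convolution block: conv2d + optional normalization + activation
#'
#' The workhorse layer. `norm = "bn"` mirrors the conv/batch-norm/SiLU triplet
#' used throughout single-stage detectors; `norm = "gn"` is the
#' group-normalized flavour used in the shared detection head (groups default
#' to the channel count, i.e. per-channel normalization).
#'
#' @param c_in,c_out channels; @param k,s kernel and stride
#' @param p padding (default "same"-style k %/% 2); @param g groups
#' @param act one of "silu", "sigmoid", "none"
#' @param norm one of "bn", "gn", "none"
#' @param bias add a bias term (default: only when norm == "none")
#' @param gn_groups groups for group norm (default c_out)
#' @return a module
#' @export
nn_conv <- function(c_in, c_out, k = 1L, s = 1L, p = NULL, g = 1L,
                    act = "silu", norm = "bn", bias = is.null(norm) || norm == "none",
                    gn_groups = NULL) {
  if (c_in %% g != 0L || c_out %% g != 0L)
    stop("conv: groups must divide both channel counts")
  p <- p %||% autopad(k)
  params <- list(w = sd_param(kaiming(c_in %/% g, k, k, c_out)))
  if (bias) params$b <- sd_param(array(0, c(c_out, 1, 1, 1)))
  norm_state <- NULL
  if (norm == "bn") {
    norm_state <- new.env(parent = emptyenv())
    norm_state$gamma <- sd_param(array(1, c(c_out, 1, 1, 1)))
    norm_state$beta <- sd_param(array(0, c(c_out, 1, 1, 1)))
    norm_state$rmean <- numeric(c_out)
    norm_state$rvar <- rep(1, c_out)
  } else if (norm == "gn") {
    params$gn_gamma <- sd_param(array(1, c(c_out, 1, 1, 1)))
    params$gn_beta <- sd_param(array(0, c(c_out, 1, 1, 1)))
  }
  new_module("conv", c_in = c_in, c_out = c_out, k = k, s = s, p = p, g = g,
             act = act, norm = norm, has_bias = bias,
             gn_groups = gn_groups %||% c_out,
             bn = norm_state, .params = params)
}

#' @export
fwd.sd_conv <- function(m, x, ...) {
  z <- op_conv2d(x, m$params$w, bias = m$params$b, stride = m$s, pad = m$p,
                 groups = m$g)
  if (m$norm == "bn") z <- op_bn(z, m$bn)
  if (m$norm == "gn") z <- op_gn(z, m$params$gn_gamma, m$params$gn_beta, m$gn_groups)
  switch(m$act, silu = op_silu(z), sigmoid = op_sigmoid(z), z)
}

#' Depthwise separable convolution (depthwise k x k then pointwise 1 x 1)
#' @param c_in,c_out channels; @param k depthwise kernel
#' @export
nn_dsconv <- function(c_in, c_out, k = 3L) {
  new_module("seq", c_out = c_out, .mods = list(
    dw = nn_conv(c_in, c_in, k = k, g = c_in),
    pw = nn_conv(c_in, c_out, k = 1L)
  ))
}

#' Sequential container
#' @param mods list of modules applied in order
#' @export
nn_seq <- function(mods) {
  new_module("seq", c_out = mods[[length(mods)]]$c_out, .mods = mods)
}

#' @export
fwd.sd_seq <- function(m, x, ...) {
  for (mm in m$mods) x <- fwd(mm, x)
  x
}

# Stable child names: positional fallbacks for unnamed submodules (sequential
# containers) so every parameter is reachable by a unique path.
mod_names <- function(m) {
  nms <- names(m$mods) %||% rep("", length(m$mods))
  blank <- !nzchar(nms)
  nms[blank] <- paste0("#", which(blank))
  nms
}

# Collect every parameter tensor in a module tree (named, depth-first).
collect_params <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  if (!is.null(m$bn)) {
    out[[paste0(prefix, "bn.gamma")]] <- m$bn$gamma
    out[[paste0(prefix, "bn.beta")]] <- m$bn$beta
  }
  nms <- mod_names(m)
  for (k in seq_along(m$mods)) {
    out <- c(out, collect_params(m$mods[[k]], paste0(prefix, nms[k], ".")))
  }
  out
}

# Walk conv/scale leaves for closed-form parameter accounting.
walk_leaves <- function(m, f) {
  if (inherits(m, "sd_conv")) f(m)
  if (inherits(m, "sd_scalepar")) f(m)
  for (mm in m$mods) walk_leaves(mm, f)
  invisible(NULL)
}

#' A learnable scalar (per-level response scaling in the detection head)
#' @param init initial value
#' @export
nn_scale <- function(init = 1) {
  new_module("scalepar", c_out = NA_integer_,
             .params = list(s = sd_param(array(init, c(1, 1, 1, 1)))))
}

#' @export
fwd.sd_scalepar <- function(m, x, ...) op_scale(x, m$params$s)
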