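# Complexity auditing: exact parameter counts, traced FLOPs at a stated input
# size, FP16 weight size, and the module-ablation ladder with row deltas.

#' Count learnable parameters
#'
#' Exact integer count of learnable scalars. `fused = TRUE` (the default, and
#' the convention of the reported figures) counts the batch-norm-folded
#' inference graph: each conv+BN pair contributes its kernel plus one bias per
#' output channel. Group-norm affine weights cannot be folded and are always
#' counted in full.
#'
#' @param model an `sd_model` or any single module
#' @param fused count the BN-folded inference graph?
#' @return integer parameter count
#' @export
count_parameters <- function(model, fused = TRUE) {
  total <- 0
  cnt <- function(m) {
    if (inherits(m, "sd_conv")) {
      wd <- dim(m$params$w$v)
      total <<- total + prod(wd)
      if (m$has_bias) total <<- total + m$c_out
      if (m$norm == "bn") total <<- total + (if (fused) m$c_out else 2L * m$c_out)
      if (m$norm == "gn") total <<- total + 2L * m$c_out
    } else if (inherits(m, "sd_scalepar")) {
      total <<- total + 1
    }
  }
  mods <- if (inherits(m <- model, "sd_model")) lapply(model$layers, `[[`, "m")
          else list(model)
  for (mm in mods) walk_leaves(mm, cnt)
  as.integer(round(total))
}

#' Estimate forward-pass FLOPs
#'
#' Traces one forward pass with a shape probe and counts 2 floating-point
#' operations per convolution multiply-accumulate (the fused-graph
#' convention: normalizations, activations and pooling are excluded from the
#' headline figure).
#'
#' @param model an `sd_model`
#' @param input_size square input side (default: the model's configured size)
#' @return GFLOPs (double)
#' @export
estimate_flops <- function(model, input_size = NULL) {
  sz <- as.integer(input_size %||% model$cfg$input_size)
  tr <- new_tracer()
  forward_model(model, sd_shape(3L, sz, sz, 1L, tracer = tr))
  2 * tr$macs / 1e9
}

#' Complexity report for one variant
#'
#' @param cfg a [variant_config()] (or a pre-built model via `model`)
#' @param model optional `sd_model` to audit directly
#' @param input_size FLOP trace input side
#' @return one-row tibble: params, gflops, fp16_mb plus the variant flags
#' @export
complexity_report <- function(cfg = variant_config(), model = NULL,
                              input_size = NULL) {
  model <- model %||% build_model(cfg)
  p <- count_parameters(model)
  tibble::tibble(
    femanet = model$cfg$use_femanet, biafa_fpn = model$cfg$use_biafa_fpn,
    adown = model$cfg$use_adown, gscdhead = model$cfg$use_gscdhead,
    params = p,
    gflops = estimate_flops(model, input_size),
    fp16_mb = p * 2 / 2^20
  )
}

#' The module-ablation complexity ladder
#'
#' Builds the five nano-scale configurations obtained by cumulatively enabling
#' the four bespoke modules and reports parameters (millions), GFLOPs at
#' 640 x 640 and FP16 weight size (MB), together with row-to-row deltas.
#'
#' @param input_size FLOP trace input side (default 640)
#' @param width_scale optional global width scaling (1 = nano)
#' @return a tibble, one row per ladder configuration
#' @export
audit_ladder <- function(input_size = 640L, width_scale = 1) {
  flags <- list(
    baseline = c(FALSE, FALSE, FALSE, FALSE),
    `+feature enhancement` = c(TRUE, FALSE, FALSE, FALSE),
    `+bidirectional fpn` = c(TRUE, TRUE, FALSE, FALSE),
    `+adaptive down` = c(TRUE, TRUE, TRUE, FALSE),
    `+shared head` = c(TRUE, TRUE, TRUE, TRUE)
  )
  rows <- lapply(names(flags), function(nm) {
    f <- flags[[nm]]
    cfg <- variant_config(f[1], f[2], f[3], f[4], width_scale = width_scale,
                          input_size = as.integer(input_size))
    r <- complexity_report(cfg)
    tibble::tibble(variant = nm, params = r$params,
                   params_m = r$params / 1e6, gflops = r$gflops,
                   fp16_mb = r$fp16_mb)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out,
                d_params_m = params_m - dplyr::lag(params_m),
                d_gflops = gflops - dplyr::lag(gflops),
                d_fp16_mb = fp16_mb - dplyr::lag(fp16_mb))
}
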