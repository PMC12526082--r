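# Checkpoint serialization: a model is stored as its variant configuration
# plus flat named parameter/buffer lists, and rebuilt by re-running the graph
# constructor. The on-disk container is whatever the caller picks (RDS from
# the CLI); this layer only produces plain R lists.

# Collect batch-norm running-stat buffers alongside parameters.
collect_buffers <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$bn)) {
    out[[paste0(prefix, "bn.rmean")]] <- m$bn$rmean
    out[[paste0(prefix, "bn.rvar")]] <- m$bn$rvar
  }
  nms <- mod_names(m)
  for (k in seq_along(m$mods))
    out <- c(out, collect_buffers(m$mods[[k]], paste0(prefix, nms[k], ".")))
  out
}

model_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers))
    out <- c(out, collect_params(model$layers[[i]]$m, paste0("l", i, ".")))
  out
}

model_buffers <- function(model) {
  out <- list()
  for (i in seq_along(model$layers))
    out <- c(out, collect_buffers(model$layers[[i]]$m, paste0("l", i, ".")))
  out
}

#' Serialize a model to a plain list
#' @param model an `sd_model`
#' @return list(cfg, params, buffers) of plain R objects
#' @export
serialize_model <- function(model) {
  list(cfg = model$cfg,
       params = lapply(model_params(model), function(p) p$v),
       buffers = model_buffers(model))
}

#' Restore a model from [serialize_model()] output
#' @param state list written by [serialize_model()]
#' @return an `sd_model` with restored weights
#' @export
unserialize_model <- function(state) {
  model <- build_model(state$cfg)
  ps <- model_params(model)
  stopifnot(identical(names(ps), names(state$params)))
  for (nm in names(ps)) ps[[nm]]$v <- state$params[[nm]]
  # restore running statistics
  for (i in seq_along(model$layers)) {
    restore_buffers(model$layers[[i]]$m, state$buffers, paste0("l", i, "."))
  }
  model
}

restore_buffers <- function(m, buffers, prefix) {
  if (!is.null(m$bn)) {
    rm_ <- buffers[[paste0(prefix, "bn.rmean")]]
    rv_ <- buffers[[paste0(prefix, "bn.rvar")]]
    if (!is.null(rm_)) m$bn$rmean <- rm_
    if (!is.null(rv_)) m$bn$rvar <- rv_
  }
  nms <- mod_names(m)
  for (k in seq_along(m$mods))
    restore_buffers(m$mods[[k]], buffers, paste0(prefix, nms[k], "."))
  invisible(NULL)
}

#' Load a model checkpoint file (RDS container)
#' @param path file written by the CLI train command
#' @export
load_model_checkpoint <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("model checkpoint not found: ", path %||% "<missing>")
  unserialize_model(readRDS(path))
}

#' Load a directory of PPM images with optional YOLO labels
#' @param dir directory of `<id>.ppm` (+ `<id>.txt`) files
#' @param ids optional id subset
#' @return list of [labeled_image()]
#' @export
load_ppm_dataset <- function(dir, ids = NULL) {
  files <- list.files(dir, pattern = "\\.ppm$", full.names = TRUE)
  if (!is.null(ids))
    files <- files[tools::file_path_sans_ext(basename(files)) %in% ids]
  lapply(files, function(f) {
    r <- read_ppm(f)
    lf <- sub("\\.ppm$", ".txt", f)
    b <- if (file.exists(lf))
      read_labels(lf, "yolo_txt", dim(r)[2], dim(r)[1]) else boxes_tbl()
    labeled_image(r, b, tools::file_path_sans_ext(basename(f)))
  })
}
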