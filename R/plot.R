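# ggplot2 displays for the main result types. ggplot2 is a suggested
# dependency; each function errors informatively when it is unavailable.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Generic autoplot (re-exported convention)
#' @param object object to plot; @param ... passed on
#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot a labeled image with its boxes
#' @param object a [labeled_image()]
#' @param max_side downsample the raster so the longer side is at most this
#' @param ... unused
#' @export
autoplot.labeled_image <- function(object, max_side = 320L, ...) {
  need_ggplot()
  r <- object$raster
  h <- dim(r)[1]; w <- dim(r)[2]
  step <- max(1L, ceiling(max(h, w) / max_side))
  ys <- seq(1L, h, by = step); xs <- seq(1L, w, by = step)
  df <- expand.grid(y = ys, x = xs)
  df$col <- grDevices::rgb(r[cbind(df$y, df$x, 1L)] / 255,
                           r[cbind(df$y, df$x, 2L)] / 255,
                           r[cbind(df$y, df$x, 3L)] / 255)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(.data$x, .data$y,
                                                 fill = I(.data$col))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = object$source_id, x = NULL, y = NULL)
  if (nrow(object$boxes)) {
    p <- p + ggplot2::geom_rect(
      data = object$boxes,
      ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                   ymin = .data$y1, ymax = .data$y2),
      fill = NA, colour = "red", linewidth = 0.3)
  }
  p
}

#' Plot the complexity ladder
#' @param object tibble from [audit_ladder()]
#' @param ... unused
#' @export
plot_ladder <- function(object, ...) {
  need_ggplot()
  df <- tidyr::pivot_longer(
    dplyr::select(object, "variant", "params_m", "gflops"),
    c("params_m", "gflops"), names_to = "measure")
  df$variant <- factor(df$variant, levels = object$variant)
  ggplot2::ggplot(df, ggplot2::aes(.data$variant, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Module-ablation complexity ladder") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Predicted-vs-true count calibration plot
#' @param y true counts; @param y_hat predicted counts
#' @param ... unused
#' @export
plot_count_calibration <- function(y, y_hat, ...) {
  need_ggplot()
  cm <- count_metrics(y, y_hat)
  ggplot2::ggplot(data.frame(y = y, y_hat = y_hat),
                  ggplot2::aes(.data$y, .data$y_hat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, colour = "darkgreen") +
    ggplot2::labs(x = "true count", y = "predicted count",
                  title = sprintf("MAE %.2f  RMSE %.2f  R2 %s", cm$mae, cm$rmse,
                                  ifelse(is.na(cm$r2), "n/a",
                                         sprintf("%.3f", cm$r2))))
}

#' Plot a training loss curve
#' @param history tibble from [train_model()]
#' @param ... unused
#' @export
plot_history <- function(history, ...) {
  need_ggplot()
  ggplot2::ggplot(history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean total loss")
}
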