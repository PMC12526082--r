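# Synthetic wheat-field scenes: dense awned ellipses on a cluttered green
# background with a controllable small/medium/large scale mixture, so the full
# pipeline (tiling, training, evaluation, counting) runs without any external
# imagery.

#' Generate one synthetic wheat-field image
#'
#' Renders Poisson-many elongated "spike" ellipses with awn strokes over a
#' textured green canopy background. The per-object scale class (largest box
#' side at the 640 px evaluation scale) is drawn from `scale_mix`, which
#' defaults to the published field statistics: 14.9% small, 77.2% medium,
#' 7.9% large. Objects are placed fully inside the canvas so annotation boxes
#' are never clipped. `style = "easy"` instead renders a few large,
#' well-separated, high-contrast ellipses on a dark background (the smoke-test
#' regime for training).
#'
#' @param width,height canvas size in pixels
#' @param lambda Poisson mean object count
#' @param scale_mix probability of small/medium/large objects (summing to 1)
#' @param occlusion_rate probability that an object is planted next to an
#'   existing one (creating overlap/occlusion)
#' @param seed RNG seed; the same seed yields byte-identical output
#' @param style "field" (default) or "easy"
#' @param source_id identifier for the produced image
#' @return a [labeled_image()]
#' @export
generate_synthetic_field <- function(width = 640L, height = 640L, lambda = 30,
                                     scale_mix = c(small = 0.149,
                                                   medium = 0.772,
                                                   large = 0.079),
                                     occlusion_rate = 0.3, seed = 0L,
                                     style = c("field", "easy"),
                                     source_id = sprintf("synth_%d", seed)) {
  style <- match.arg(style)
  stopifnot(width >= 32L, height >= 32L, lambda > 0,
            abs(sum(scale_mix) - 1) < 1e-6)
  with_local_seed(seed, {
    if (style == "easy") {
      img <- render_background(width, height, base = c(25, 30, 22), amp = 6)
      n <- sample(3:6, 1)
      sizes <- stats::runif(n, 90, 180) * max(width, height) / 640
      render_spikes(img, sizes, width, height, occlusion_rate = 0,
                    min_sep = 1.3, color = c(235, 215, 120), jitter = 10,
                    source_id = source_id)
    } else {
      img <- render_background(width, height, base = c(62, 92, 38), amp = 22)
      n <- stats::rpois(1, lambda)
      cls <- sample(names(scale_mix), n, replace = TRUE, prob = scale_mix)
      # object scale = max box side at the 640-eval resolution; sample within
      # each category band, then convert to native pixels
      s640 <- ifelse(cls == "small", stats::runif(n, 14, 31.5),
              ifelse(cls == "medium", stats::runif(n, 33, 94),
                     stats::runif(n, 98, 150)))
      sizes <- s640 * max(width, height) / 640
      render_spikes(img, sizes, width, height, occlusion_rate = occlusion_rate,
                    min_sep = 0, color = c(172, 162, 88), jitter = 28,
                    source_id = source_id)
    }
  })
}

# Low-frequency mottle + speckle background.
render_background <- function(w, h, base, amp) {
  gy <- sin(seq(0, 6 * pi, length.out = h) + stats::runif(1, 0, 2 * pi))
  gx <- sin(seq(0, 5 * pi, length.out = w) + stats::runif(1, 0, 2 * pi))
  mottle <- outer(gy, gx) * amp / 2
  speckle <- matrix(stats::rnorm(h * w, sd = amp / 2), h, w)
  img <- array(0, c(h, w, 3L))
  for (k in 1:3) img[, , k] <- pmin(pmax(base[k] + mottle + speckle, 0), 255)
  img
}

# Paint rotated ellipses with awn strokes; returns a labeled_image.
render_spikes <- function(img, sizes, w, h, occlusion_rate, min_sep, color,
                          jitter, source_id) {
  n <- length(sizes)
  boxes <- NULL
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    L <- sizes[i]                               # target max box side
    aspect <- stats::runif(1, 0.3, 0.55)
    theta <- stats::runif(1, 0, pi)
    # semi-axes such that the axis-aligned bounding box of the rotated
    # ellipse has max side exactly L: the box half-sides are
    # bx = sqrt(a^2 cos^2 + b^2 sin^2), by = sqrt(a^2 sin^2 + b^2 cos^2)
    ct <- cos(theta)^2; st <- sin(theta)^2
    a <- L / 2 / sqrt(max(ct + aspect^2 * st, st + aspect^2 * ct))
    b <- a * aspect
    margin <- L / 2 + 2
    if (margin * 2 >= min(w, h)) next
    ok <- FALSE
    for (try in 1:25) {
      if (nrow(centers) && stats::runif(1) < occlusion_rate) {
        k <- sample(nrow(centers), 1)
        cx <- centers[k, 1] + stats::rnorm(1, sd = L / 2)
        cy <- centers[k, 2] + stats::rnorm(1, sd = L / 2)
      } else {
        cx <- stats::runif(1, margin, w - margin)
        cy <- stats::runif(1, margin, h - margin)
      }
      if (cx < margin || cx > w - margin || cy < margin || cy > h - margin) next
      if (min_sep > 0 && nrow(centers)) {
        dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(dd < min_sep * L)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) next
    col <- pmin(pmax(color + stats::rnorm(3, sd = jitter), 0), 255)
    # paint the ellipse within its bounding patch
    r <- ceiling(a) + 1
    xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    core <- (u / a)^2 + (v / (0.6 * b))^2 <= 0.55
    if (!any(inside)) next
    for (k in 1:3) {
      plane <- img[ys, xs, k]
      plane[inside] <- col[k] * 0.85 + plane[inside] * 0.15
      plane[core] <- pmin(col[k] * 1.12, 255)
      img[ys, xs, k] <- plane
    }
    # awns: short bright strokes beyond both ellipse tips
    for (tip in c(-1, 1)) {
      tx <- cx + tip * a * cos(theta); ty <- cy + tip * a * sin(theta)
      for (s in seq(0, a * 0.25, length.out = 6)) {
        px <- round(tx + tip * s * cos(theta + stats::rnorm(1, sd = 0.25)))
        py <- round(ty + tip * s * sin(theta + stats::rnorm(1, sd = 0.25)))
        if (px >= 1 && px <= w && py >= 1 && py <= h)
          img[py, px, ] <- pmin(col * 1.1, 255)
      }
    }
    # axis-aligned bounding box of the painted ellipse, clipped to canvas
    bx <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    by <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
    boxes <- rbind(boxes, c(max(0, cx - bx), max(0, cy - by),
                            min(w, cx + bx), min(h, cy + by)))
    centers <- rbind(centers, c(cx, cy))
  }
  b <- if (is.null(boxes)) boxes_tbl() else
    boxes_tbl(boxes[, 1], boxes[, 2], boxes[, 3], boxes[, 4], 0L)
  labeled_image(img, b, source_id)
}

#' Generate a synthetic dataset
#'
#' @param n number of images
#' @param seed base seed; image i uses seed + i
#' @param dir optional output directory: writes `<id>.ppm` rasters and
#'   YOLO-format `<id>.txt` labels
#' @param ... forwarded to [generate_synthetic_field()]
#' @return invisible list of labeled images
#' @export
generate_synthetic_dataset <- function(n, seed = 0L, dir = NULL, ...) {
  imgs <- lapply(seq_len(n), function(i)
    generate_synthetic_field(seed = seed + i, ...,
                             source_id = sprintf("synth_%04d", i)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (im in imgs) {
      write_ppm(im$raster, file.path(dir, paste0(im$source_id, ".ppm")))
      write_labels(im$boxes, file.path(dir, paste0(im$source_id, ".txt")),
                   "yolo_txt", image_width = dim(im$raster)[2],
                   image_height = dim(im$raster)[1])
    }
  }
  invisible(imgs)
}
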