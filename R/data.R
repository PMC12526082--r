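# Dataset engineering: labeled images, overlap tiling with white padding,
# deterministic splits, COCO scale categories, and annotation / raster I/O.
# Boxes travel as tibbles with columns x1, y1, x2, y2, class_id using 0-based,
# half-open pixel coordinates [x1, x2) x [y1, y2).

#' Create a box tibble
#' @param x1,y1,x2,y2 corner coordinates (0-based, half-open)
#' @param class_id integer class labels (default 0)
#' @return a tibble with one row per box
#' @export
boxes_tbl <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), class_id = 0L) {
  tb <- tibble::tibble(x1 = as.numeric(x1), y1 = as.numeric(y1),
                       x2 = as.numeric(x2), y2 = as.numeric(y2),
                       class_id = as.integer(rep_len(class_id, length(x1))))
  bad <- tb$x1 >= tb$x2 | tb$y1 >= tb$y2
  if (any(bad)) stop("boxes_tbl: degenerate box (x1 >= x2 or y1 >= y2)")
  tb
}

#' A labeled image
#' @param raster H x W x 3 numeric array with values in 0-255
#' @param boxes a box tibble (see [boxes_tbl()])
#' @param source_id identifier string
#' @return a `labeled_image`
#' @export
labeled_image <- function(raster, boxes = boxes_tbl(), source_id = "img") {
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] == 3L)
  h <- dim(raster)[1]; w <- dim(raster)[2]
  if (nrow(boxes) && (min(boxes$x1, boxes$y1) < 0 || max(boxes$x2) > w ||
                      max(boxes$y2) > h))
    stop("labeled_image: boxes exceed raster bounds")
  structure(list(raster = raster, boxes = boxes, source_id = source_id),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$raster)
  cat("<labeled_image '", x$source_id, "' ", d[1], "x", d[2], ", ",
      nrow(x$boxes), " boxes>\n", sep = "")
  invisible(x)
}

#' Tile an image on an overlapping grid with white padding
#'
#' Tiles are laid from the origin with stride
#' `round(tile_size * (1 - overlap_fraction))`; partial edge tiles are padded
#' to the full tile size with white. Every source pixel is covered by at least
#' one tile. Boxes are translated into tile coordinates and clipped; clipped
#' boxes retaining less than `min_retention` of their original area are
#' dropped.
#'
#' @param img a [labeled_image()]
#' @param tile_size square tile side in pixels (1024 by default)
#' @param overlap_fraction fractional overlap between neighbouring tiles
#' @param pad_value white padding value
#' @param min_retention minimum retained area fraction for a clipped box
#' @return a `tile_set`: list of tiles (each a labeled_image plus its origin
#'   offset), the tile size and the overlap fraction
#' @export
tile_image <- function(img, tile_size = 1024L, overlap_fraction = 0.10,
                       pad_value = 255, min_retention = 0.2) {
  stopifnot(inherits(img, "labeled_image"), tile_size >= 1L,
            overlap_fraction >= 0, overlap_fraction < 1)
  h <- dim(img$raster)[1]; w <- dim(img$raster)[2]
  stride <- max(1L, as.integer(round(tile_size * (1 - overlap_fraction))))
  offsets <- function(total) {
    n <- if (total <= tile_size) 1L
         else as.integer(ceiling((total - tile_size) / stride)) + 1L
    (seq_len(n) - 1L) * stride
  }
  xs <- offsets(w); ys <- offsets(h)
  area <- (img$boxes$x2 - img$boxes$x1) * (img$boxes$y2 - img$boxes$y1)
  tiles <- list()
  for (oy in ys) for (ox in xs) {
    raster <- array(pad_value, c(tile_size, tile_size, 3L))
    hh <- min(tile_size, h - oy); ww <- min(tile_size, w - ox)
    raster[seq_len(hh), seq_len(ww), ] <-
      img$raster[oy + seq_len(hh), ox + seq_len(ww), , drop = FALSE]
    b <- img$boxes
    if (nrow(b)) {
      cx1 <- pmax(b$x1 - ox, 0); cy1 <- pmax(b$y1 - oy, 0)
      cx2 <- pmin(b$x2 - ox, tile_size); cy2 <- pmin(b$y2 - oy, tile_size)
      keep <- cx2 > cx1 & cy2 > cy1 &
        (cx2 - cx1) * (cy2 - cy1) >= min_retention * area
      b <- boxes_tbl(cx1[keep], cy1[keep], cx2[keep], cy2[keep],
                     b$class_id[keep])
    }
    tiles[[length(tiles) + 1L]] <- list(
      image = labeled_image(raster, b,
                            sprintf("%s_x%d_y%d", img$source_id, ox, oy)),
      offset = c(x = ox, y = oy))
  }
  structure(list(tiles = tiles, tile_size = as.integer(tile_size),
                 overlap_fraction = overlap_fraction, stride = stride,
                 source_dim = c(h = h, w = w)),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat("<tile_set: ", length(x$tiles), " tiles of ", x$tile_size, "px, stride ",
      x$stride, ">\n", sep = "")
  invisible(x)
}

#' Categorize object scale (COCO convention at evaluation resolution)
#'
#' The scale of an object is the larger of its width or height, rescaled from
#' the native image resolution to the evaluation input size (640 px). Objects
#' under 32 px are small, those in [32, 96) medium, and those at or above
#' 96 px large (boundaries are assigned upward).
#'
#' @param boxes a box tibble, or numeric widths
#' @param heights numeric heights when `boxes` is a width vector
#' @param native_size native image side in pixels
#' @param eval_size evaluation input side (640)
#' @return factor with levels small / medium / large
#' @export
categorize_scale <- function(boxes, heights = NULL, native_size = 640,
                             eval_size = 640) {
  if (is.data.frame(boxes)) {
    w <- boxes$x2 - boxes$x1
    h <- boxes$y2 - boxes$y1
  } else {
    w <- boxes; h <- heights
  }
  s <- pmax(w, h) * eval_size / native_size
  cut(s, breaks = c(-Inf, 32, 96, Inf), labels = c("small", "medium", "large"),
      right = FALSE)
}

#' Deterministic train/validation/test split
#'
#' Shuffles ids with a local RNG seeded by `seed`, then assigns the leading
#' splits `floor(N * ratio)` items each with the final split absorbing the
#' remainder, so sizes always sum to N (this reproduces the published 7:2:1
#' subset sizes, e.g. 6035/1724/863 from 8622).
#'
#' @param item_ids vector of ids (length >= number of splits)
#' @param ratio split proportions, default `c(7, 2, 1)`
#' @param seed RNG seed
#' @return named list of disjoint id vectors: train, val, test
#' @export
split_dataset <- function(item_ids, ratio = c(7, 2, 1), seed = 0L) {
  stopifnot(length(item_ids) >= length(ratio), all(ratio > 0))
  r <- ratio / sum(ratio)
  n <- length(item_ids)
  sizes <- floor(n * r)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  perm <- with_local_seed(seed, sample.int(n))
  ids <- item_ids[perm]
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_along(sizes), function(i) ids[starts[i]:ends[i]])
  names(out) <- if (length(out) == 3L) c("train", "val", "test")
                else paste0("split", seq_along(out))
  out
}

# Run expr under a temporary RNG state (byte-reproducible, caller-isolated).
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# ---- annotation I/O ---------------------------------------------------------

#' Read bounding-box labels
#'
#' `yolo_txt` files hold one `class cx cy w h` line per box with coordinates
#' normalized to the image size; `coco_json` holds absolute `[x, y, w, h]`
#' boxes grouped by image. Malformed records raise an error naming the file
#' and line.
#'
#' @param path label file
#' @param format "yolo_txt" or "coco_json"
#' @param image_width,image_height raster dims (required for yolo_txt)
#' @return for yolo_txt a box tibble; for coco_json a named list of box
#'   tibbles, one per image, with image dims in attributes
#' @export
read_labels <- function(path, format = c("yolo_txt", "coco_json"),
                        image_width = NULL, image_height = NULL) {
  format <- match.arg(format)
  if (format == "yolo_txt") {
    stopifnot(!is.null(image_width), !is.null(image_height))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(boxes_tbl())
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 5L)
    if (length(bad))
      stop(sprintf("%s:%d: expected 5 fields in YOLO label line", path, bad[1]))
    m <- suppressWarnings(do.call(rbind, lapply(parts, as.numeric)))
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1, any))[1]
      stop(sprintf("%s:%d: non-numeric YOLO label field", path, bad))
    }
    cx <- m[, 2] * image_width; cy <- m[, 3] * image_height
    w <- m[, 4] * image_width; h <- m[, 5] * image_height
    boxes_tbl(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2, as.integer(m[, 1]))
  } else {
    js <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     stop(sprintf("%s: malformed COCO JSON (%s)", path,
                                  conditionMessage(e))))
    if (is.null(js$images) || is.null(js$annotations))
      stop(sprintf("%s: COCO JSON lacks images/annotations", path))
    out <- list()
    for (i in seq_len(nrow(js$images))) {
      im <- js$images[i, ]
      ann <- js$annotations[js$annotations$image_id == im$id, , drop = FALSE]
      b <- if (nrow(ann)) {
        bb <- do.call(rbind, ann$bbox)
        boxes_tbl(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4],
                  as.integer(ann$category_id))
      } else boxes_tbl()
      attr(b, "width") <- im$width; attr(b, "height") <- im$height
      out[[im$file_name]] <- b
    }
    out
  }
}

#' Write bounding-box labels
#'
#' @param boxes a box tibble (yolo_txt) or named list of box tibbles
#'   (coco_json, names are file names)
#' @param path output file
#' @param format "yolo_txt" or "coco_json"
#' @param image_width,image_height raster dims (yolo_txt and coco_json)
#' @return `path`, invisibly
#' @export
write_labels <- function(boxes, path, format = c("yolo_txt", "coco_json"),
                         image_width = NULL, image_height = NULL) {
  format <- match.arg(format)
  if (format == "yolo_txt") {
    stopifnot(is.data.frame(boxes), !is.null(image_width), !is.null(image_height))
    lines <- sprintf("%d %.9f %.9f %.9f %.9f", boxes$class_id,
                     (boxes$x1 + boxes$x2) / 2 / image_width,
                     (boxes$y1 + boxes$y2) / 2 / image_height,
                     (boxes$x2 - boxes$x1) / image_width,
                     (boxes$y2 - boxes$y1) / image_height)
    writeLines(lines, path)
  } else {
    if (is.data.frame(boxes)) boxes <- list(image = boxes)
    images <- list(); anns <- list(); aid <- 0L
    for (i in seq_along(boxes)) {
      b <- boxes[[i]]
      wdt <- attr(b, "width") %||% image_width
      hgt <- attr(b, "height") %||% image_height
      images[[i]] <- list(id = i, file_name = names(boxes)[i],
                          width = wdt, height = hgt)
      if (nrow(b)) for (j in seq_len(nrow(b))) {
        aid <- aid + 1L
        anns[[aid]] <- list(id = aid, image_id = i,
                            category_id = b$class_id[j],
                            bbox = c(b$x1[j], b$y1[j], b$x2[j] - b$x1[j],
                                     b$y2[j] - b$y1[j]),
                            area = (b$x2[j] - b$x1[j]) * (b$y2[j] - b$y1[j]),
                            iscrowd = 0L)
      }
    }
    jsonlite::write_json(
      list(images = images, annotations = anns,
           categories = list(list(id = 0L, name = "spike"))),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- portable anymap raster I/O ---------------------------------------------

#' Write an RGB raster as portable pixmap (PPM)
#'
#' @param raster H x W x 3 array, values 0-255
#' @param path output file
#' @param ascii write text (P3) instead of binary (P6)
#' @return `path`, invisibly
#' @export
write_ppm <- function(raster, path, ascii = FALSE) {
  h <- dim(raster)[1]; w <- dim(raster)[2]
  v <- as.integer(round(pmin(pmax(raster, 0), 255)))
  # interleave to R,G,B per pixel, row-major
  px <- aperm(array(v, dim(raster)), c(3, 2, 1))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(as.vector(px), collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.vector(px)), con)
  }
  invisible(path)
}

#' Read a portable pixmap (P3 or P6)
#' @param path PPM file
#' @return H x W x 3 numeric array (0-255)
#' @export
read_ppm <- function(path) {
  if (!file.exists(path)) stop("PPM file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- ppm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P3", "P6")) stop(path, ": not a P3/P6 PPM file")
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  if (anyNA(c(w, h, mx))) stop(path, ": malformed PPM header")
  n <- 3L * w * h
  v <- if (magic == "P6") {
    as.integer(readBin(con, "raw", n))
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      chunk <- readLines(con, n = 64L, warn = FALSE)
      if (!length(chunk)) break
      vals <- c(vals, as.integer(unlist(strsplit(trimws(chunk), "\\s+"))))
    }
    if (length(vals) < n) stop(path, ": truncated P3 payload")
    vals[seq_len(n)]
  }
  aperm(array(v, c(3L, w, h)), c(3, 2, 1))
}

# Whitespace/comment-aware single-token reader for PNM headers; stops after
# the final header token so binary payload alignment is preserved.
ppm_tokenizer <- function(con) {
  function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("unexpected end of PNM header")
      if (ch == "#") {
        while (length(ch) && ch != "\n") ch <- readChar(con, 1L, useBytes = TRUE)
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[ \t\r\n]", ch)) return(tok)
      tok <- paste0(tok, ch)
    }
  }
}
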