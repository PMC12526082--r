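# Data engineering: overlap tiling with white padding, scale categories,
# deterministic splits, and annotation / raster round-trips.

mk_img <- function(h, w, boxes = boxes_tbl(), val = 100) {
  labeled_image(array(val, c(h, w, 3L)), boxes, sprintf("t%dx%d", h, w))
}

test_that("tiling: exact fit yields one unpadded tile", {
  im <- mk_img(1024, 1024)
  ts <- tile_image(im)
  expect_length(ts$tiles, 1L)
  expect_true(all(ts$tiles[[1]]$image$raster == 100))
})

test_that("tiling: large image tiles are all the declared size", {
  im <- mk_img(384, 512)
  ts <- tile_image(im, tile_size = 128L, overlap_fraction = 0.10)
  expect_true(all(vapply(ts$tiles, function(t)
    all(dim(t$image$raster)[1:2] == 128L), logical(1))))
  expect_equal(ts$stride, 115L)  # round(128 * 0.9)
})

test_that("tiling: the 1100px case forms a 2x2 grid with white-padded margins", {
  b <- boxes_tbl(c(10, 1050), c(10, 1050), c(100, 1090), c(100, 1090))
  im <- mk_img(1100, 1100, b)
  ts <- tile_image(im)  # stride 922
  expect_length(ts$tiles, 4L)
  offs <- t(vapply(ts$tiles, `[[`, numeric(2), "offset"))
  expect_setequal(paste(offs[, 1], offs[, 2]), c("0 0", "922 0", "0 922", "922 922"))
  last <- ts$tiles[[4]]$image$raster
  expect_true(all(last[, 200:1024, ] == 255))   # padding beyond source extent
  expect_true(all(last[1:178, 1:178, ] == 100)) # source region preserved
  # coverage: every source pixel appears in at least one tile
  covered_x <- logical(1100)
  for (o in unique(offs[, 1])) covered_x[(o + 1):min(o + 1024, 1100)] <- TRUE
  expect_true(all(covered_x))
  # the corner box lands untouched in tile 1; the far box in tile 4
  expect_equal(nrow(ts$tiles[[1]]$image$boxes), 1L)
  expect_equal(ts$tiles[[4]]$image$boxes$x1, 1050 - 922)
})

test_that("tiling drops clipped boxes below the retention threshold", {
  # a 100x100 box with only 10x100 inside the second tile: 10% < 20% retained
  b <- boxes_tbl(50, 10, 150, 110)
  im <- mk_img(200, 300, b)
  ts <- tile_image(im, tile_size = 140L, overlap_fraction = 0)
  # tile at x offset 140 contains 10px of the box width -> dropped
  t2 <- ts$tiles[[which(vapply(ts$tiles, function(t) t$offset[["x"]] == 140,
                               logical(1)))[1]]]
  expect_equal(nrow(t2$image$boxes), 0L)
  t1 <- ts$tiles[[which(vapply(ts$tiles, function(t) t$offset[["x"]] == 0,
                               logical(1)))[1]]]
  expect_equal(nrow(t1$image$boxes), 1L)
})

test_that("tiling coverage invariant holds over 200 random image sizes", {
  set.seed(501)
  for (i in 1:200) {
    h <- sample(1:200, 1); w <- sample(1:200, 1)
    tile <- sample(c(32L, 64L, 100L), 1)
    ov <- runif(1, 0, 0.3)
    stride <- max(1L, as.integer(round(tile * (1 - ov))))
    n_off <- function(total) if (total <= tile) 1L else
      as.integer(ceiling((total - tile) / stride)) + 1L
    # arithmetic coverage check mirrors the tiler's grid
    ts <- tile_image(mk_img(h, w), tile, ov)
    offs <- t(vapply(ts$tiles, `[[`, numeric(2), "offset"))
    cx <- logical(w); cy <- logical(h)
    for (o in unique(offs[, 1])) cx[(o + 1):min(o + tile, w)] <- TRUE
    for (o in unique(offs[, 2])) cy[(o + 1):min(o + tile, h)] <- TRUE
    if (!(all(cx) && all(cy))) fail(sprintf("uncovered at %dx%d tile %d", h, w, tile))
  }
  succeed()
})

test_that("scale categories follow the COCO bands at evaluation resolution", {
  expect_equal(as.character(categorize_scale(30, 20, native_size = 640)), "small")
  expect_equal(as.character(categorize_scale(80, 40, native_size = 1024)),
               "medium")  # 80 * 640/1024 = 50
  expect_equal(as.character(categorize_scale(96, 10, native_size = 640)),
               "large")   # boundary assigned upward
  expect_equal(as.character(categorize_scale(32, 32, native_size = 640)),
               "medium")  # lower boundary assigned upward too
  # every box gets a category (partition)
  set.seed(502)
  w <- runif(500, 1, 300); h <- runif(500, 1, 300)
  expect_false(anyNA(categorize_scale(w, h, native_size = 640)))
})

test_that("splits reproduce the published 7:2:1 subset sizes", {
  s <- split_dataset(seq_len(8622), seed = 1)
  expect_equal(lengths(s), c(train = 6035L, val = 1724L, test = 863L))
  s2 <- split_dataset(seq_len(6422), seed = 1)
  expect_equal(lengths(s2), c(train = 4495L, val = 1284L, test = 643L))
  s3 <- split_dataset(seq_len(10), seed = 1)
  expect_equal(lengths(s3), c(train = 7L, val = 2L, test = 1L))
})

test_that("splits are a reproducible partition", {
  set.seed(503)
  for (i in 1:20) {
    n <- sample(3:500, 1)
    seed <- sample(1e6, 1)
    ids <- paste0("img", seq_len(n))
    a <- split_dataset(ids, seed = seed)
    b <- split_dataset(ids, seed = seed)
    expect_identical(a, b)
    expect_equal(sort(unname(unlist(a))), sort(ids))
    expect_equal(sum(lengths(a)), n)
    expect_equal(anyDuplicated(unlist(a)), 0L)
  }
})

test_that("YOLO label round-trip and denormalization arithmetic", {
  tmp <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.1 0.2", tmp)
  b <- read_labels(tmp, "yolo_txt", image_width = 640, image_height = 640)
  expect_equal(unlist(b[1, 1:4]), c(x1 = 288, y1 = 256, x2 = 352, y2 = 384))
  set.seed(504)
  bb <- boxes_tbl(runif(5, 0, 300), runif(5, 0, 300),
                  runif(5, 320, 640), runif(5, 320, 640),
                  class_id = 0:4)
  write_labels(bb, tmp, "yolo_txt", 640, 640)
  back <- read_labels(tmp, "yolo_txt", 640, 640)
  expect_equal(as.data.frame(back), as.data.frame(bb), tolerance = 1e-6)
})

test_that("empty and malformed label files behave as specified", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(character(0), tmp)
  expect_equal(nrow(read_labels(tmp, "yolo_txt", 100, 100)), 0L)
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5"), tmp)
  expect_error(read_labels(tmp, "yolo_txt", 100, 100), ":2:")
  writeLines("0 0.5 foo 0.1 0.1", tmp)
  expect_error(read_labels(tmp, "yolo_txt", 100, 100), "non-numeric")
})

test_that("COCO JSON round-trip preserves boxes and image dims", {
  set.seed(505)
  b1 <- boxes_tbl(c(0, 10), c(5, 20), c(50, 60), c(55, 80))
  attr(b1, "width") <- 100; attr(b1, "height") <- 120
  b2 <- boxes_tbl()
  attr(b2, "width") <- 64; attr(b2, "height") <- 64
  tmp <- tempfile(fileext = ".json")
  write_labels(list(a.ppm = b1, b.ppm = b2), tmp, "coco_json")
  back <- read_labels(tmp, "coco_json")
  expect_named(back, c("a.ppm", "b.ppm"))
  expect_equal(as.data.frame(back$a.ppm), as.data.frame(b1), tolerance = 1e-9)
  expect_equal(nrow(back$b.ppm), 0L)
  expect_equal(attr(back$a.ppm, "width"), 100)
})

test_that("PPM raster I/O round-trips in binary and text modes", {
  set.seed(506)
  r <- array(sample(0:255, 12 * 9 * 3, replace = TRUE), c(12, 9, 3))
  f6 <- tempfile(fileext = ".ppm"); f3 <- tempfile(fileext = ".ppm")
  write_ppm(r, f6)
  write_ppm(r, f3, ascii = TRUE)
  expect_equal(read_ppm(f6), r + 0)
  expect_equal(read_ppm(f3), r + 0)
  expect_error(read_ppm(tempfile()), "cannot open|No such|not")
})
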