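test_that("PNG and TIFF color images round-trip pixel-identically", {
  set.seed(1)
  px <- array(sample(0:255, 40 * 30 * 3, replace = TRUE), dim = c(40, 30, 3))
  img <- color_image(px, 1.5)
  for (ext in c(".png", ".tif")) {
    p <- withr::local_tempfile(fileext = ext)
    write_color_image(img, p)
    back <- read_color_image(p, 1.5)
    expect_identical(back$pixels, img$pixels, label = ext)
    expect_equal(back$scale_px_per_um, 1.5)
  }
  # 1x1 pure red pixel
  one <- color_image(array(c(255L, 0L, 0L), dim = c(1, 1, 3)))
  p <- withr::local_tempfile(fileext = ".png")
  write_color_image(one, p)
  expect_equal(as.vector(read_color_image(p)$pixels[1, 1, ]), c(255, 0, 0))
})

test_that("RGBA is alpha-stripped and greyscale is rejected", {
  p <- withr::local_tempfile(fileext = ".png")
  rgba <- array(runif(6 * 5 * 4), dim = c(6, 5, 4))
  png::writePNG(rgba, p)
  img <- read_color_image(p)
  expect_equal(dim(img$pixels), c(6, 5, 3))
  grey <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(30), 6, 5), grey)
  expect_error(read_color_image(grey), class = "perivasc_format_error")
})

test_that("non-8-bit and compressed TIFFs are rejected with format errors", {
  # hand-written 1x1 16-bit RGB TIFF
  p <- withr::local_tempfile(fileext = ".tif")
  con <- file(p, "wb")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); w2(42L); w4(20L)
  writeBin(as.raw(rep(255, 6)), con)           # pixel data (3 x 16 bit) at 8
  w2(c(16L, 16L, 16L))                         # BitsPerSample block at 14
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3 && count == 1) { w2(value); w2(0L) } else w4(value)
  }
  w2(8L)
  entry(256L, 3L, 1L, 1L); entry(257L, 3L, 1L, 1L)
  entry(258L, 3L, 3L, 14L); entry(259L, 3L, 1L, 1L)
  entry(262L, 3L, 1L, 2L); entry(273L, 4L, 1L, 8L)
  entry(277L, 3L, 1L, 3L); entry(279L, 4L, 1L, 6L)
  w4(0L)
  close(con)
  expect_error(read_color_image(p), class = "perivasc_format_error")

  # compressed flag set -> rejected
  img <- color_image(array(128L, dim = c(4, 4, 3)))
  q <- withr::local_tempfile(fileext = ".tif")
  write_color_image(img, q)
  raw <- readBin(q, "raw", file.size(q))
  ifd <- readBin(raw[5:8], "integer", size = 4, endian = "little")
  # entry 4 (compression) value field lies at ifd + 2 + 3*12 + 8
  raw[ifd + 2 + 3 * 12 + 8 + 1] <- as.raw(5)
  writeBin(raw, q)
  expect_error(read_color_image(q), class = "perivasc_format_error")

  expect_error(read_color_image(withr::local_tempfile(fileext = ".tif")),
               class = "perivasc_io_error")
})

test_that("mask PNG round-trips exactly", {
  set.seed(2)
  m <- random_mask(17, 23)
  p <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, p)
  expect_identical(read_mask_png(p), m)
})

test_that("ROI JSON round-trips and uses 0-based file coordinates", {
  roi <- roi_spec(list(rbind(c(3, 3), c(3, 6), c(6, 6), c(6, 3))),
                  list(rbind(c(4, 4), c(4, 5), c(5, 5), c(5, 4))))
  p <- withr::local_tempfile(fileext = ".json")
  write_roi(roi, p)
  doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_equal(unlist(doc$include[[1]][[1]]), c(2, 2))  # 0-based on disk
  roi2 <- read_roi(p)
  expect_identical(rasterize_roi(roi2, c(10, 10)), rasterize_roi(roi, c(10, 10)))
})

test_that("rasterize_roi matches brute-force membership and edge conventions", {
  full <- roi_spec(list(rbind(c(0.5, 0.5), c(0.5, 10.5), c(10.5, 10.5), c(10.5, 0.5))))
  expect_true(all(rasterize_roi(full, c(10, 10))))
  cancel <- roi_spec(full$include, full$include)
  expect_false(any(rasterize_roi(cancel, c(10, 10))))

  # axis-aligned rectangle with vertices on pixel centers: boundary included
  rect <- roi_spec(list(rbind(c(3, 3), c(3, 6), c(6, 6), c(6, 3))))
  m <- rasterize_roi(rect, c(10, 10))
  brute <- outer(1:10, 1:10, function(r, c) r >= 3 & r <= 6 & c >= 3 & c <= 6)
  expect_identical(m, brute)
  expect_equal(mask_area(m), 16)

  # triangle vs brute-force half-plane test
  tri <- rbind(c(1, 1), c(1, 9), c(9, 1))
  m2 <- rasterize_roi(roi_spec(list(tri)), c(10, 10))
  brute2 <- outer(1:10, 1:10, function(r, c) r + c <= 10 & r >= 1 & c >= 1)
  expect_identical(m2, brute2)

  expect_error(roi_spec(list(rbind(c(1, 1), c(2, 2)))),
               class = "perivasc_validation_error")
})

test_that("rasterize_roi is monotone in its polygon lists", {
  set.seed(3)
  shape <- c(20, 20)
  rand_rect <- function() {
    r <- sort(runif(2, 1, 20)); c <- sort(runif(2, 1, 20))
    rbind(c(r[1], c[1]), c(r[1], c[2]), c(r[2], c[2]), c(r[2], c[1]))
  }
  for (i in 1:20) {
    inc <- list(rand_rect()); exc <- list(rand_rect())
    base <- rasterize_roi(roi_spec(inc, exc), shape)
    more_inc <- rasterize_roi(roi_spec(c(inc, list(rand_rect())), exc), shape)
    expect_true(all(base <= more_inc))
    more_exc <- rasterize_roi(roi_spec(inc, c(exc, list(rand_rect()))), shape)
    expect_true(all(more_exc <= base))
  }
})

test_that("results table round-trips with full precision and validates input", {
  fx <- make_fixture(tiny_spec(rng_seed = 5))
  res <- analyze_image(fx$image, fx$roi, widths_um = c(10, 20),
                       image_id = "im1", patient_id = "P01")
  p <- withr::local_tempfile(fileext = ".csv")
  write_results_table(res, p)
  back <- read_results_table(p)
  expect_equal(nrow(back), 2)
  expect_equal(back$F_N, res$F_N, tolerance = 1e-12)
  expect_equal(back$F_D, res$F_D, tolerance = 1e-12)
  expect_identical(back$image_id, res$image_id)
  expect_error(write_results_table(res[0, ], p),
               class = "perivasc_validation_error")
  expect_error(write_results_table(data.frame(a = 1), p),
               class = "perivasc_validation_error")
})
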