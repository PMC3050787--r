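#' Read an 8-bit RGB micrograph
#'
#' Reads a TIFF or PNG micrograph into a `color_image` object.  Only 8
#' bit/channel images are accepted; RGBA inputs have their alpha channel
#' stripped, greyscale inputs are rejected (a two-color stain cannot be
#' segmented from a single channel).
#'
#' @param path path to an 8-bit RGB TIFF (uncompressed baseline) or PNG.
#' @param scale_px_per_um physical scale of the image in pixels per
#'   micrometer.  The default 1.5 corresponds to a scale bar of
#'   100 µm = 150 px, the calibration of the original micrographs.
#' @return a `color_image`: list with `pixels` (H x W x 3 integer array,
#'   values 0-255, channels in R,G,B order) and `scale_px_per_um`.
#' @seealso [write_color_image()], [rasterize_roi()]
#' @export
read_color_image <- function(path, scale_px_per_um = 1.5) {
  if (!is.numeric(scale_px_per_um) || length(scale_px_per_um) != 1L ||
      !is.finite(scale_px_per_um) || scale_px_per_um <= 0)
    pv_validation_error("scale_px_per_um must be a positive number")
  if (!file.exists(path)) pv_io_error("cannot read image '%s': no such file", path)
  ext <- tolower(tools::file_ext(path))
  pixels <- switch(ext,
    tif = , tiff = read_tiff_rgb(path),
    png = read_png_rgb(path),
    pv_format_error("unsupported image format '.%s' (TIFF or PNG expected)", ext))
  color_image(pixels, scale_px_per_um)
}

read_png_rgb <- function(path) {
  arr <- tryCatch(png::readPNG(path, info = TRUE), error = function(e)
    pv_io_error("cannot read PNG '%s': %s", path, conditionMessage(e)))
  info <- attr(arr, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 8L)
    pv_format_error("PNG '%s': %d-bit depth unsupported (8-bit only)",
                    path, info$bit.depth)
  if (length(dim(arr)) < 3L || dim(arr)[3] < 3L)
    pv_format_error("PNG '%s' is not an RGB image (greyscale input rejected)",
                    path)
  px <- array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3L))
  px
}

#' Construct or write a color image
#'
#' @param pixels H x W x 3 integer array with values in 0..255.
#' @param scale_px_per_um positive scale in pixels per micrometer.
#' @return `color_image()` returns the validated object;
#'   `write_color_image()` writes it (format chosen by file extension:
#'   `.tif`/`.tiff` uncompressed TIFF, `.png` PNG) and returns `path`
#'   invisibly.
#' @export
color_image <- function(pixels, scale_px_per_um = 1.5) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    pv_validation_error("pixels must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    pv_validation_error("image must have H >= 1, W >= 1")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    pv_validation_error("channel values must lie in [0, 255]")
  if (!is.numeric(scale_px_per_um) || scale_px_per_um <= 0)
    pv_validation_error("scale_px_per_um must be > 0")
  structure(list(pixels = pixels, scale_px_per_um = as.numeric(scale_px_per_um)),
            class = "color_image")
}

#' @rdname color_image
#' @param image a `color_image`.
#' @param path output file path.
#' @export
write_color_image <- function(image, path) {
  stopifnot(inherits(image, "color_image"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = write_tiff_rgb(image$pixels, path),
    png = png::writePNG(image$pixels / 255, path),
    pv_format_error("unsupported image format '.%s' (TIFF or PNG expected)", ext))
  invisible(path)
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<color_image %d x %d px, %.3g px/um (%.4g x %.4g um)>\n",
              d[1], d[2], x$scale_px_per_um,
              d[1] / x$scale_px_per_um, d[2] / x$scale_px_per_um))
  invisible(x)
}

#' Persist / load binary masks as PNG
#'
#' Masks are stored as single-channel 8-bit PNG with values 0 (FALSE) and
#' 255 (TRUE).
#'
#' @param mask logical matrix.
#' @param path file path ending in `.png`.
#' @return `read_mask_png()` returns a logical matrix; `write_mask_png()`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- tryCatch(png::readPNG(path), error = function(e)
    pv_io_error("cannot read mask PNG '%s': %s", path, conditionMessage(e)))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr > 0.5
}

# ---- region-of-interest polygons -------------------------------------------

#' Region-of-interest specification
#'
#' An ROI stands in for the interactive specimen outline of the original
#' workflow: the analyzable specimen is the union of the include polygons
#' minus the union of the exclude polygons (vessel lumina, glands,
#' off-section background).  Polygons are closed vertex lists in pixel
#' coordinates, `(row, col)` order.  In R, vertices are given 1-based (like
#' matrix indices); the JSON file format stores them 0-based.
#'
#' @param include list of polygons (each an n x 2 numeric matrix of
#'   `(row, col)` vertices, n >= 3).
#' @param exclude list of polygons to subtract.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(include, exclude = list()) {
  norm <- function(polys, what) {
    lapply(polys, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
        pv_validation_error("each %s polygon needs >= 3 (row, col) vertices", what)
      storage.mode(p) <- "double"
      colnames(p) <- c("row", "col")
      p
    })
  }
  structure(list(include = norm(include, "include"),
                 exclude = norm(exclude, "exclude")),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @param path JSON file of the form
#'   `{"include": [[[r,c], ...], ...], "exclude": [...]}` with 0-based
#'   pixel coordinates.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) pv_io_error("cannot read ROI '%s': no such file", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    pv_format_error("ROI '%s' is not valid JSON: %s", path,
                                    conditionMessage(e)))
  grab <- function(key) {
    polys <- doc[[key]]
    if (is.null(polys)) return(list())
    # 0-based file coordinates -> 1-based R matrix coordinates
    lapply(polys, function(p)
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))) + 1)
  }
  roi_spec(grab("include"), grab("exclude"))
}

#' @rdname roi_spec
#' @param roi an `roi_spec`.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  to0 <- function(polys) lapply(polys, function(p) unname(p - 1))
  jsonlite::write_json(list(include = to0(roi$include),
                            exclude = to0(roi$exclude)),
                       path, digits = NA)
  invisible(path)
}

# even-odd point-in-polygon over pixel centers, vectorized over points.
# Pixel (i, j) has its center at continuous coordinates (i, j); a center
# lying exactly on a polygon edge counts as inside.
points_in_polygon <- function(pr, pc, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  r1s <- poly[, 1]; c1s <- poly[, 2]
  r2s <- poly[c(2:n, 1), 1]; c2s <- poly[c(2:n, 1), 2]
  for (e in seq_len(n)) {
    r1 <- r1s[e]; c1 <- c1s[e]; r2 <- r2s[e]; c2 <- c2s[e]
    # on-segment test: zero cross product + inside bounding box
    cross <- (r2 - r1) * (pc - c1) - (c2 - c1) * (pr - r1)
    on_edge <- on_edge | (abs(cross) <= eps *
                            (abs(r2 - r1) + abs(c2 - c1) + 1) &
                          pr >= pmin(r1, r2) - eps & pr <= pmax(r1, r2) + eps &
                          pc >= pmin(c1, c2) - eps & pc <= pmax(c1, c2) + eps)
    if (r1 == r2) next  # horizontal edge never crossed by the ray rule
    crosses <- ((r1 > pr) != (r2 > pr)) &
      (pc < c1 + (pr - r1) * (c2 - c1) / (r2 - r1))
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Rasterize an ROI to a binary specimen mask
#'
#' A pixel is `TRUE` iff its center lies inside (even-odd rule, boundary
#' inclusive) some include polygon and inside no exclude polygon.
#'
#' @param roi an [roi_spec()].
#' @param shape integer `(H, W)` of the target image.
#' @return logical `H x W` mask.
#' @examples
#' roi <- roi_spec(list(rbind(c(3, 3), c(3, 6), c(6, 6), c(6, 3))))
#' mask_area(rasterize_roi(roi, c(10, 10)))  # 16
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi_spec"))
  if (length(shape) != 2L || any(shape < 1))
    pv_validation_error("shape must be (H, W) with H, W >= 1")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  paint <- function(polys) {
    m <- matrix(FALSE, H, W)
    for (p in polys) {
      rlo <- max(1L, floor(min(p[, 1]))); rhi <- min(H, ceiling(max(p[, 1])))
      clo <- max(1L, floor(min(p[, 2]))); chi <- min(W, ceiling(max(p[, 2])))
      if (rlo > rhi || clo > chi) next
      rows <- rlo:rhi; cols <- clo:chi
      grid_r <- rep(rows, times = length(cols))
      grid_c <- rep(cols, each = length(rows))
      hit <- points_in_polygon(grid_r, grid_c, p)
      m[rows, cols] <- m[rows, cols] | matrix(hit, length(rows), length(cols))
    }
    m
  }
  paint(roi$include) & !paint(roi$exclude)
}

# ---- results table ---------------------------------------------------------

RESULT_COLUMNS <- c("image_id", "patient_id", "width_um", "kernel_px",
                    "area_T", "area_B", "area_N", "area_D",
                    "area_NR", "area_DR", "area_BR", "F_N", "F_D", "ratio")

#' Write / read the per-image neighborhood results table
#'
#' One CSV row per (image, neighborhood width).  `area_BR` (red pixels lying
#' on the structure itself, counted in neither fraction) is included for
#' audit.  Floats are written at full double precision.
#'
#' @param results data.frame of neighborhood results, as returned by
#'   [analyze_image()] (possibly row-bound over images).
#' @param path CSV output path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns the data.frame.
#' @export
write_results_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    pv_validation_error("results must be a nonempty data.frame")
  missing_cols <- setdiff(RESULT_COLUMNS, names(results))
  if (length(missing_cols))
    pv_validation_error("results lack columns: %s",
                        paste(missing_cols, collapse = ", "))
  ok <- tryCatch({
    write.csv(results[, RESULT_COLUMNS], path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) pv_io_error("cannot write results table '%s'", path)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) pv_io_error("cannot read results '%s': no such file", path)
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(image_id = "character", patient_id = "character"))
}
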