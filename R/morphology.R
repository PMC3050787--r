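#' Binary morphology with square structuring elements
#'
#' `dilate_mask()` performs binary dilation with a solid, centered square
#' structuring element of side `kernel_px` (odd).  Equivalently, the output
#' is `TRUE` at any pixel whose Chebyshev distance to a `TRUE` input pixel
#' is at most `(kernel_px - 1) / 2`.  For dilation the image border behaves
#' as if padded with `FALSE` (tissue outside the frame is unknown and
#' excluded from the specimen anyway); for `erode_mask()` the border is
#' padded with `TRUE` so that `close_mask()` (dilate then erode) cannot eat
#' objects touching the frame edge — the usual convention of image-analysis
#' toolboxes.  `open_mask()` is erode then dilate.
#'
#' A disk-shaped (Euclidean) element is available via `shape = "disk"`,
#' where `kernel_px` is the disk diameter; the default is the square
#' element, matching the square kernel matrices of the method.
#'
#' @param mask logical matrix.
#' @param kernel_px odd positive integer side (or disk diameter).
#' @param shape `"square"` (default) or `"disk"`.
#' @return logical matrix of the same shape.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
#' mask_area(dilate_mask(m, 5))  # 25
#' @export
dilate_mask <- function(mask, kernel_px, shape = c("square", "disk")) {
  assert_mask(mask)
  shape <- match.arg(shape)
  check_kernel(kernel_px)
  if (shape == "square") return(cpp_dilate_square(mask, as.integer(kernel_px)))
  dilate_disk(mask, kernel_px)
}

check_kernel <- function(kernel_px) {
  if (!is.numeric(kernel_px) || length(kernel_px) != 1L ||
      kernel_px < 1 || kernel_px %% 2 != 1)
    pv_validation_error("kernel_px must be an odd positive integer")
  invisible(kernel_px)
}

# disk SE as a union of row strips: for each vertical offset dy the strip
# half-width is floor(sqrt(r^2 - dy^2))
dilate_disk <- function(mask, kernel_px) {
  r <- (kernel_px - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (dy in -r:r) {
    rx <- floor(sqrt(r^2 - dy^2))
    shifted <- matrix(FALSE, H, W)
    src <- seq_len(H) - dy
    keep <- src >= 1 & src <= H
    shifted[which(keep), ] <- mask[src[keep], , drop = FALSE]
    out <- out | cpp_dilate_rect(shifted, 1L, as.integer(2 * rx + 1))
  }
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, kernel_px, shape = c("square", "disk")) {
  assert_mask(mask)
  shape <- match.arg(shape)
  check_kernel(kernel_px)
  if (shape == "square") return(cpp_erode_square(mask, as.integer(kernel_px)))
  !dilate_disk(!mask, kernel_px)
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, kernel_px, shape = c("square", "disk"))
  erode_mask(dilate_mask(mask, kernel_px, shape), kernel_px, shape)

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, kernel_px, shape = c("square", "disk"))
  dilate_mask(erode_mask(mask, kernel_px, shape), kernel_px, shape)

#' Connected-component labeling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the blob convention used when
#'   scrapping small objects).
#' @return integer matrix of component labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  cpp_label_components(mask, as.integer(connectivity))
}
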