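#' Binary masks
#'
#' Throughout the package a binary mask is a plain logical `H x W` matrix.
#' Pixel `[i, j]` (1-based in R code) is the pixel in image row `i`, column
#' `j`, with row 1 at the top of the image.  In serialized formats (ROI JSON,
#' mask PNG) coordinates are 0-based `(row, col)`; the R API uses ordinary
#' 1-based matrix indexing.
#'
#' @param mask logical matrix.
#' @return `mask_area()` returns the number of `TRUE` pixels as an integer.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[2:3, 2:3] <- TRUE
#' mask_area(m)  # 4
#' @export
mask_area <- function(mask) {
  assert_mask(mask)
  sum(mask)
}

assert_mask <- function(mask, name = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !is.logical(mask))
    pv_validation_error("%s must be a logical matrix", name)
  if (anyNA(mask))
    pv_validation_error("%s contains NA pixels", name)
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    pv_validation_error("%s have mismatched shapes (%s vs %s)", what,
                        paste(dim(a)[1:2], collapse = "x"),
                        paste(dim(b)[1:2], collapse = "x"))
  invisible(NULL)
}
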