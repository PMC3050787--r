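#' Segmentation parameters
#'
#' Tunables of the two-color segmentation:
#' * `ratio_threshold` — a pixel belongs to the target stain when its target
#'   channel is at least this factor times *each* of the other two channels
#'   ("at least 60% higher" = 1.6, the default).  Must exceed 1.
#' * `red_cleanup_kernel_px` — side of the square element for the
#'   closing-then-opening cleanup of the red cell mask.  The original
#'   description names the operations but not the element size; 3 is the
#'   smallest element that removes single-pixel noise.
#' * `blue_min_object_fraction` — connected blue objects smaller than this
#'   fraction of the specimen area are scrapped (default 0.0001, i.e.
#'   0.01% of A_T).
#' * `blue_closing_kernel_px` — side of the square closing element applied
#'   to the blue structure mask after scrapping (default 11).
#' * `connectivity` — pixel connectivity for blob labeling (default 8).
#'
#' @param ratio_threshold numeric > 1.
#' @param red_cleanup_kernel_px odd positive integer.
#' @param blue_min_object_fraction numeric in (0, 1).
#' @param blue_closing_kernel_px odd positive integer.
#' @param connectivity 4 or 8.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(ratio_threshold = 1.6,
                                red_cleanup_kernel_px = 3L,
                                blue_min_object_fraction = 1e-4,
                                blue_closing_kernel_px = 11L,
                                connectivity = 8L) {
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 1)
    pv_validation_error("ratio_threshold must be > 1")
  check_kernel(red_cleanup_kernel_px)
  check_kernel(blue_closing_kernel_px)
  if (!is.numeric(blue_min_object_fraction) ||
      blue_min_object_fraction <= 0 || blue_min_object_fraction >= 1)
    pv_validation_error("blue_min_object_fraction must be in (0, 1)")
  if (!connectivity %in% c(4L, 8L))
    pv_validation_error("connectivity must be 4 or 8")
  structure(list(ratio_threshold = ratio_threshold,
                 red_cleanup_kernel_px = as.integer(red_cleanup_kernel_px),
                 blue_min_object_fraction = blue_min_object_fraction,
                 blue_closing_kernel_px = as.integer(blue_closing_kernel_px),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Segment the total specimen area A_T
#'
#' Rasterizes the ROI to the binary specimen mask.  This mask serves as the
#' clipping mask for every subsequent processing step.
#'
#' @param image a [color_image()].
#' @param roi an [roi_spec()].
#' @return logical mask A_T.
#' @export
segment_total <- function(image, roi) {
  stopifnot(inherits(image, "color_image"))
  rasterize_roi(roi, dim(image$pixels)[1:2])
}

#' Relative-RGB-plane stain segmentation
#'
#' A pixel is assigned to the target stain iff its target channel grey
#' value is at least `ratio_threshold` times the grey value of *each* of
#' the two other channels (inclusive comparison, in real arithmetic on the
#' raw 8-bit values), and the pixel lies inside the specimen mask.  For
#' `target_channel = "red"` the rule is `R >= t*G && R >= t*B`; for
#' `"blue"` the roles of R and B swap.  The relative rule is insensitive to
#' common intensity scaling of a pixel, which is what makes it robust to
#' staining and illumination variation.
#'
#' @param image a [color_image()].
#' @param target_channel `"red"` (mobile cells) or `"blue"` (fixed
#'   structure).
#' @param params [segmentation_params()].
#' @param a_t specimen mask A_T (logical matrix, same shape as the image).
#' @return logical mask of the raw (uncleaned) segmentation.
#' @export
segment_relative_color <- function(image, target_channel = c("red", "blue"),
                                   params = segmentation_params(), a_t) {
  stopifnot(inherits(image, "color_image"))
  target_channel <- match.arg(target_channel)
  assert_mask(a_t)
  assert_same_shape(image$pixels, a_t, "image and A_T")
  px <- image$pixels
  t <- params$ratio_threshold
  R <- px[, , 1]; G <- px[, , 2]; B <- px[, , 3]
  hit <- if (target_channel == "red") (R >= t * G) & (R >= t * B)
         else (B >= t * G) & (B >= t * R)
  hit & a_t
}

#' Cleanup of the raw red-cell mask (yields A_R)
#'
#' Morphological closing then opening with a square element of side
#' `red_cleanup_kernel_px`, removing residual noise and granular texture;
#' the result is re-intersected with A_T so border effects cannot leak
#' outside the specimen.
#'
#' @param mask raw red segmentation (logical matrix).
#' @param params [segmentation_params()].
#' @param a_t specimen mask; if `NULL`, no re-masking is applied.
#' @return logical mask A_R.
#' @export
clean_red_mask <- function(mask, params = segmentation_params(), a_t = NULL) {
  assert_mask(mask)
  k <- params$red_cleanup_kernel_px
  out <- open_mask(close_mask(mask, k), k)
  if (!is.null(a_t)) {
    assert_same_shape(mask, a_t)
    out <- out & a_t
  }
  out
}

#' Cleanup of the raw blue-structure mask (yields A_B)
#'
#' Connected components smaller than `blue_min_object_fraction * area(A_T)`
#' pixels are scrapped (deleted), then a moderate closing with an 11 x 11
#' square element is applied; the result is re-intersected with A_T.
#'
#' @param mask raw blue segmentation (logical matrix).
#' @param params [segmentation_params()].
#' @param a_t specimen mask A_T (required: the scrapping threshold is a
#'   fraction of its area).
#' @return logical mask A_B.
#' @export
clean_blue_mask <- function(mask, params = segmentation_params(), a_t) {
  assert_mask(mask)
  assert_mask(a_t)
  assert_same_shape(mask, a_t)
  min_px <- params$blue_min_object_fraction * mask_area(a_t)
  lab <- label_components(mask, params$connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- sizes >= min_px
    mask <- mask & matrix(c(FALSE, keep)[lab + 1L], nrow(lab), ncol(lab))
  }
  close_mask(mask, params$blue_closing_kernel_px) & a_t
}
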