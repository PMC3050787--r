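#' Dilation kernel size for a neighborhood width
#'
#' The graded neighborhoods are built by dilating the structure mask with
#' square kernels.  A neighborhood of physical width `w` µm at scale `s`
#' px/µm needs a kernel of side `2 * round(w * s) + 1` pixels.  At the
#' reference calibration of 1.5 px/µm (100 µm = 150 px scale bar) this
#' yields the series 31, 61, 91, ... px for widths 10, 20, 30, ... µm.
#' Non-integral `w * s` is rounded half-up to the nearest integer
#' half-width.
#'
#' @param width_um neighborhood width in micrometers (> 0).
#' @param scale_px_per_um scale in pixels per micrometer (> 0).
#' @return odd positive integer kernel side.
#' @examples
#' kernel_px_for_width(10, 1.5)  # 31
#' kernel_px_for_width(30, 1.5)  # 91
#' @export
kernel_px_for_width <- function(width_um, scale_px_per_um) {
  if (!is.numeric(width_um) || any(width_um <= 0) || anyNA(width_um))
    pv_validation_error("width_um must be positive")
  if (!is.numeric(scale_px_per_um) || length(scale_px_per_um) != 1L ||
      scale_px_per_um <= 0)
    pv_validation_error("scale_px_per_um must be positive")
  as.integer(2 * floor(width_um * scale_px_per_um + 0.5) + 1)
}

#' Neighborhood and residual areas around a structure
#'
#' Dilates the structure mask A_B with a square kernel, clips to the
#' specimen, and splits the specimen into the neighborhood area
#' `A_N = (dilated  minus A_B)` and the residual area `A_D = A_T minus
#' dilated`.  A_N, A_D and A_B are pairwise disjoint and partition A_T
#' exactly.
#'
#' @param structure_b structure mask A_B (must be a subset of `a_t` and
#'   nonempty).
#' @param a_t specimen mask A_T.
#' @param kernel_px odd positive kernel side, see [kernel_px_for_width()].
#' @param clip_to_specimen clip the dilated area to A_T before subtracting
#'   (default `TRUE`); without clipping, neighborhood pixels could fall in
#'   excluded lumina or background.
#' @param shape structuring element shape, `"square"` or `"disk"`.
#' @return list with logical masks `a_n` and `a_d`.
#' @export
neighborhood_areas <- function(structure_b, a_t, kernel_px,
                               clip_to_specimen = TRUE,
                               shape = c("square", "disk")) {
  assert_mask(structure_b); assert_mask(a_t)
  assert_same_shape(structure_b, a_t)
  if (!any(structure_b))
    pv_degenerate_error("structure mask A_B is empty: neighborhood analysis is undefined")
  if (any(structure_b & !a_t))
    pv_validation_error("structure mask A_B must be a subset of A_T")
  dil <- dilate_mask(structure_b, kernel_px, match.arg(shape))
  if (clip_to_specimen) dil <- dil & a_t
  list(a_n = dil & !structure_b, a_d = a_t & !dil)
}

#' Density fractions of the neighborhood and residual areas
#'
#' `F_N = |A_R AND A_N| / |A_N|` and `F_D = |A_R AND A_D| / |A_D|`: the
#' fractions of the neighborhood / residual area occupied by red-stained
#' cell pixels.  Both are dimensionless in `[0, 1]`, so no physical-unit
#' conversion is ever needed; their ratio is the enrichment measure.
#'
#' @param a_r red cell mask A_R.
#' @param a_n neighborhood mask A_N.
#' @param a_d residual mask A_D.
#' @return list with `F_N` and `F_D`.
#' @export
density_fractions <- function(a_r, a_n, a_d) {
  assert_mask(a_r); assert_mask(a_n); assert_mask(a_d)
  assert_same_shape(a_r, a_n); assert_same_shape(a_r, a_d)
  n_n <- sum(a_n); n_d <- sum(a_d)
  if (n_n == 0L || n_d == 0L)
    pv_degenerate_error(
      "undefined density fraction: %s has zero area",
      paste(c("A_N", "A_D")[c(n_n == 0L, n_d == 0L)], collapse = " and "),
      data = list(empty = c(A_N = n_n == 0L, A_D = n_d == 0L)))
  list(F_N = sum(a_r & a_n) / n_n, F_D = sum(a_r & a_d) / n_d)
}

#' Full per-image neighborhood analysis
#'
#' Runs the complete morphometric chain for one micrograph: specimen
#' masking, relative-RGB segmentation of red cells and blue structure with
#' their morphological cleanups, then for every requested neighborhood
#' width the graded areas and density fractions.
#'
#' @param image a [color_image()].
#' @param roi an [roi_spec()].
#' @param widths_um strictly increasing vector of neighborhood widths in
#'   µm; defaults to 10-50 µm in 10 µm steps.
#' @param params [segmentation_params()].
#' @param image_id,patient_id identifiers carried into the results table.
#' @param clip_to_specimen see [neighborhood_areas()].
#' @param keep_masks if `TRUE`, attach the segmentation masks
#'   (`a_t`, `a_r`, `a_b`) as an attribute `"masks"` for audit.
#' @return data.frame with one row per width and the columns of
#'   [write_results_table()]: pixel areas `area_T/B/N/D/NR/DR/BR`,
#'   fractions `F_N`, `F_D` and their `ratio` (NA when `F_D = 0`).
#' @export
analyze_image <- function(image, roi, widths_um = c(10, 20, 30, 40, 50),
                          params = segmentation_params(),
                          image_id = "image", patient_id = NA_character_,
                          clip_to_specimen = TRUE, keep_masks = FALSE) {
  if (length(widths_um) < 1L || is.unsorted(widths_um, strictly = TRUE))
    pv_validation_error("widths_um must be strictly increasing")
  a_t <- segment_total(image, roi)
  if (!any(a_t))
    pv_degenerate_error("specimen area A_T is empty")
  a_r <- clean_red_mask(segment_relative_color(image, "red", params, a_t),
                        params, a_t)
  a_b <- clean_blue_mask(segment_relative_color(image, "blue", params, a_t),
                         params, a_t)
  a_r_off <- a_r & !a_b  # red on the structure itself counts in no fraction
  rows <- lapply(widths_um, function(w) {
    k <- kernel_px_for_width(w, image$scale_px_per_um)
    nb <- neighborhood_areas(a_b, a_t, k, clip_to_specimen)
    fr <- density_fractions(a_r_off, nb$a_n, nb$a_d)
    data.frame(image_id = image_id, patient_id = patient_id,
               width_um = w, kernel_px = k,
               area_T = mask_area(a_t), area_B = mask_area(a_b),
               area_N = mask_area(nb$a_n), area_D = mask_area(nb$a_d),
               area_NR = sum(a_r_off & nb$a_n), area_DR = sum(a_r_off & nb$a_d),
               area_BR = sum(a_r & a_b),
               F_N = fr$F_N, F_D = fr$F_D,
               ratio = if (fr$F_D > 0) fr$F_N / fr$F_D else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (keep_masks) attr(out, "masks") <- list(a_t = a_t, a_r = a_r, a_b = a_b)
  out
}
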