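#' Specification of a synthetic two-color micrograph
#'
#' The fixture generator emulates the image classes the method operates on:
#' a light background (tissue), a blue-stained fixed structure (vessel
#' endothelium ring, a set of vessel cross-section blobs, or a branching
#' vessel curve), and red-stained mobile cells scattered with an optional
#' planted perivascular enrichment.  Cells are placed by rejection
#' sampling: a candidate seed inside the enrichment band (within
#' `enrichment_band_um` of the structure) is accepted with probability
#' proportional to `enrichment_factor`, outside with probability
#' proportional to 1, so `enrichment_factor = 1` gives spatially uniform
#' placement and the planted neighborhood/residual density ratio at the
#' band width is the factor itself.
#'
#' Default colors sit far from the 1.6 relative-RGB decision boundary (red
#' cells (200, 60, 60); blue structure (60, 60, 200); background
#' (235, 225, 225)), so the noise-free image segments back to the planted
#' masks pixel-exactly and mild channel noise cannot flip a pixel.
#'
#' @param frame integer `(H, W)` in pixels (default 256 x 256, a ~171 µm
#'   field at the default scale).
#' @param scale_px_per_um scale (default 1.5, i.e. 100 µm = 150 px).
#' @param structure list describing the fixed structure; `type` one of
#'   `"ring"` (fields `radius_px`, `thickness_px`, auto-generates a lumen
#'   exclude polygon), `"blobs"` (`n`, `radius_px`) or `"branching"`
#'   (`n_branches`, `thickness_px`).
#' @param n_cells number of red cells (default 30, a stained-area fraction
#'   of about 6% on the default frame).
#' @param cell_area_px target pixel area per cell (default 110, a ~10 µm
#'   diameter cell at the default scale, the size class of uterine NK
#'   cells; cells much smaller than the cleanup element would be eroded
#'   by the morphological opening).
#' @param enrichment_factor relative in-band placement density (default 1).
#' @param enrichment_band_um band width in µm (default 10).
#' @param lumen_polygons extra ROI exclude polygons (1-based `(row, col)`).
#' @param colors list with `red`, `blue`, `background` RGB triples.
#' @param noise_sd additive Gaussian channel noise SD (default 0).
#' @param growth_connectivity cell growth connectivity (default 4).
#' @param rng_seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(frame = c(256L, 256L), scale_px_per_um = 1.5,
                         structure = list(type = "ring"),
                         n_cells = 30L, cell_area_px = 110L,
                         enrichment_factor = 1, enrichment_band_um = 10,
                         lumen_polygons = list(),
                         colors = list(red = c(200L, 60L, 60L),
                                       blue = c(60L, 60L, 200L),
                                       background = c(235L, 225L, 225L)),
                         noise_sd = 0, growth_connectivity = 4L,
                         rng_seed = 1L) {
  if (length(frame) != 2L || any(frame < 32))
    pv_validation_error("frame must be (H, W), both >= 32")
  if (enrichment_factor <= 0)
    pv_validation_error("enrichment_factor must be positive")
  if (enrichment_band_um <= 0)
    pv_validation_error("enrichment_band_um must be positive")
  structure(list(frame = as.integer(frame), scale_px_per_um = scale_px_per_um,
                 structure = structure, n_cells = as.integer(n_cells),
                 cell_area_px = as.integer(cell_area_px),
                 enrichment_factor = enrichment_factor,
                 enrichment_band_um = enrichment_band_um,
                 lumen_polygons = lumen_polygons, colors = colors,
                 noise_sd = noise_sd,
                 growth_connectivity = as.integer(growth_connectivity),
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

circle_polygon <- function(center, radius, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(row = center[1] + radius * sin(th), col = center[2] + radius * cos(th))
}

# structure mask + auto lumen polygons for a fixture frame
make_structure <- function(spec) {
  H <- spec$frame[1]; W <- spec$frame[2]
  ctr <- c(H, W) / 2
  g <- spec$structure
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  lumen <- list()
  type <- if (is.null(g$type)) "ring" else g$type
  if (type == "ring") {
    radius <- if (is.null(g$radius_px)) round(0.22 * min(H, W)) else g$radius_px
    thick <- if (is.null(g$thickness_px)) 5L else g$thickness_px
    d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    mask <- d >= radius - thick / 2 & d <= radius + thick / 2
    # lumen exclusion drawn flush against the vessel wall (slightly
    # overlapping the inner pixel layer), as an interactive ROI would be:
    # a gap narrower than a cell would trap filament-shaped cells that the
    # red-mask opening then erases, biasing the neighborhood density
    lumen <- list(circle_polygon(ctr, radius - thick / 2 + 1, n = 36L))
  } else if (type == "blobs") {
    n <- if (is.null(g$n)) 4L else g$n
    radius <- if (is.null(g$radius_px)) round(0.05 * min(H, W)) else g$radius_px
    mask <- matrix(FALSE, H, W)
    margin <- radius + 2
    for (i in seq_len(n)) {
      c_i <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      mask <- mask | (sqrt((rr - c_i[1])^2 + (cc - c_i[2])^2) <= radius)
    }
  } else if (type == "branching") {
    n_br <- if (is.null(g$n_branches)) 3L else g$n_branches
    thick <- if (is.null(g$thickness_px)) 5L else g$thickness_px
    mask <- matrix(FALSE, H, W)
    pos <- ctr
    for (b in seq_len(n_br)) {
      ang <- runif(1, 0, 2 * pi)
      len <- round(0.3 * min(H, W))
      steps <- seq(0, len)
      r_path <- round(pos[1] + steps * sin(ang))
      c_path <- round(pos[2] + steps * cos(ang))
      ok <- r_path >= 1 & r_path <= H & c_path >= 1 & c_path <= W
      mask[cbind(r_path[ok], c_path[ok])] <- TRUE
      i_mid <- max(which(ok))
      pos <- c(r_path[i_mid], c_path[i_mid]) / 2 + ctr / 2
    }
    mask <- dilate_mask(mask, 2L * (thick %/% 2L) + 1L)
  } else {
    pv_validation_error("unknown structure type '%s'", type)
  }
  list(mask = mask, lumen = lumen)
}

#' Generate one synthetic micrograph with known ground truth
#'
#' @param spec a [fixture_spec()].
#' @return list with `image` (a [color_image()]), `roi` (an [roi_spec()]:
#'   full-frame include, lumen excludes), and `truth`: masks `a_t`, `a_b`,
#'   `a_r` plus the planted `centers` (n x 2 matrix of seed pixels) and
#'   the effective `band` mask.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$rng_seed)
  H <- spec$frame[1]; W <- spec$frame[2]
  st <- make_structure(spec)
  include <- list(rbind(c(0.5, 0.5), c(0.5, W + 0.5),
                        c(H + 0.5, W + 0.5), c(H + 0.5, 0.5)))
  roi <- roi_spec(include, c(st$lumen, spec$lumen_polygons))
  a_t <- rasterize_roi(roi, c(H, W))
  a_b <- st$mask & a_t
  if (!any(a_b)) pv_validation_error("structure lies entirely outside the ROI")
  if (spec$n_cells * spec$cell_area_px >= 0.5 * sum(a_t))
    pv_validation_error("infeasible density: planted cell area >= 50%% of A_T")
  allowed <- a_t & !a_b
  band_px <- kernel_px_for_width(spec$enrichment_band_um, spec$scale_px_per_um)
  band <- dilate_mask(a_b, band_px) & allowed
  # rejection-sample seeds: acceptance proportional to the enrichment factor
  # inside the band, to 1 outside
  ef <- spec$enrichment_factor
  p_in <- ef / max(ef, 1); p_out <- 1 / max(ef, 1)
  idx_allowed <- which(allowed)
  in_band <- band[idx_allowed]
  seeds <- integer(0)
  if (spec$n_cells > 0L) {
    while (length(seeds) < spec$n_cells) {
      need <- spec$n_cells - length(seeds)
      cand <- idx_allowed[sample.int(length(idx_allowed), max(2L * need, 32L),
                                     replace = TRUE)]
      acc <- runif(length(cand)) < ifelse(band[cand], p_in, p_out)
      seeds <- unique(c(seeds, cand[acc]))
    }
    seeds <- seeds[seq_len(spec$n_cells)]
    sr <- (seeds - 1L) %% H
    sc <- (seeds - 1L) %/% H
    a_r <- cpp_grow_cells(allowed, sr, sc, spec$cell_area_px,
                          spec$growth_connectivity)
  } else {
    a_r <- matrix(FALSE, H, W)
  }
  px <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) {
    plane <- matrix(spec$colors$background[ch], H, W)
    plane[a_b] <- spec$colors$blue[ch]
    plane[a_r] <- spec$colors$red[ch]
    if (spec$noise_sd > 0)
      plane <- plane + rnorm(H * W, 0, spec$noise_sd)
    px[, , ch] <- pmax(0L, pmin(255L, as.integer(round(plane))))
  }
  centers <- cbind(row = (seeds - 1L) %% H + 1L, col = (seeds - 1L) %/% H + 1L)
  list(image = color_image(px, spec$scale_px_per_um), roi = roi,
       truth = list(a_t = a_t, a_b = a_b, a_r = a_r,
                    centers = centers, band = band))
}

#' Generate a synthetic patient cohort
#'
#' Mirrors the study design (one to a few tissue samples per patient):
#' per-patient enrichment factors are drawn around `effect` on the log
#' scale (`log-SD` `effect_sdlog`, default 0.25) to create realistic
#' between-patient variation; each sample of a patient is an independent
#' fixture at that patient's factor.  With `effect = 1` the per-patient
#' log-factors are symmetric about 0, so the pipeline's test operates under
#' its null.
#'
#' @param n_patients number of patients (>= 2).
#' @param samples_per_patient samples per patient.
#' @param spec base [fixture_spec()]; per-sample seeds are derived from the
#'   ambient RNG (call `set.seed()` first for reproducibility).
#' @param effect central enrichment factor.
#' @param effect_sdlog between-patient log-SD of the factor.
#' @param dir if non-`NULL`, writes `<image_id>.tif`, `<image_id>.roi.json`
#'   and `mapping.csv` into `dir` and returns the mapping; otherwise
#'   returns the in-memory fixtures.
#' @return list with `mapping` (data.frame image_id, patient_id),
#'   `factors` (per patient), and — when `dir` is `NULL` — `fixtures`
#'   (named list of [make_fixture()] outputs).
#' @export
make_cohort <- function(n_patients, samples_per_patient = 1L, spec = fixture_spec(),
                        effect = 1, effect_sdlog = 0.25, dir = NULL) {
  if (n_patients < 2L) pv_validation_error("n_patients must be >= 2")
  factors <- effect * exp(rnorm(n_patients, 0, effect_sdlog))
  mapping <- expand.grid(sample = seq_len(samples_per_patient),
                         patient = seq_len(n_patients))
  mapping <- data.frame(
    image_id = sprintf("P%02dS%02d", mapping$patient, mapping$sample),
    patient_id = sprintf("P%02d", mapping$patient),
    stringsAsFactors = FALSE)
  fixtures <- vector("list", nrow(mapping))
  names(fixtures) <- mapping$image_id
  for (i in seq_len(nrow(mapping))) {
    pat <- as.integer(substr(mapping$patient_id[i], 2, 3))
    spec_i <- spec
    spec_i$enrichment_factor <- factors[pat]
    spec_i$rng_seed <- sample.int(.Machine$integer.max, 1L)
    fixtures[[i]] <- make_fixture(spec_i)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(mapping))) {
      id <- mapping$image_id[i]
      write_color_image(fixtures[[i]]$image, file.path(dir, paste0(id, ".tif")))
      write_roi(fixtures[[i]]$roi, file.path(dir, paste0(id, ".roi.json")))
    }
    write.csv(mapping, file.path(dir, "mapping.csv"), row.names = FALSE)
    return(invisible(list(mapping = mapping, factors = factors, dir = dir)))
  }
  list(mapping = mapping, factors = factors, fixtures = fixtures)
}
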