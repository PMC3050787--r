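#' Configuration of the random-distribution simulation study
#'
#' The null model scatters artificial cells uniformly over the specimen of
#' a given sample geometry and measures the same density fractions as the
#' real analysis.  Defaults follow the original study design: seed counts
#' 100-500 in steps of 100, with 100 replicate images per count (500
#' images altogether).
#'
#' @param seed_counts vector of positive integers, cells per image.
#' @param replicates_per_count replicate images per seed count.
#' @param target_cell_area_px target pixel area of each grown artificial
#'   cell; choose to match the size of real cells, e.g. via
#'   [estimate_cell_area()] on a real red mask (default 110 px, a ~10 µm
#'   cell at 1.5 px/µm).
#' @param rng_seed integer seed governing the whole study.
#' @param growth_connectivity 4 (default; compact blobs) or 8.
#' @param placement `"overlay"` (default) or `"constrained"`, see
#'   [generate_random_cell_image()].  The overlay mode reproduces the
#'   original procedure — cells are scattered over the whole frame, grown
#'   freely, and the parts inside the vessel or outside the specimen are
#'   eliminated afterwards — and is the spatially unbiased null; the
#'   constrained mode confines growth to the specimen, which concentrates
#'   cell mass against the structure boundary and biases the neighborhood
#'   density upward for cell sizes comparable to the neighborhood width.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed_counts = c(100L, 200L, 300L, 400L, 500L),
                              replicates_per_count = 100L,
                              target_cell_area_px = 110L,
                              rng_seed = 1L,
                              growth_connectivity = 4L,
                              placement = c("overlay", "constrained")) {
  if (any(seed_counts < 0) || anyNA(seed_counts))
    pv_validation_error("seed_counts must be nonnegative integers")
  if (replicates_per_count < 1)
    pv_validation_error("replicates_per_count must be >= 1")
  if (target_cell_area_px < 1)
    pv_validation_error("target_cell_area_px must be >= 1")
  if (!growth_connectivity %in% c(4L, 8L))
    pv_validation_error("growth_connectivity must be 4 or 8")
  structure(list(seed_counts = as.integer(seed_counts),
                 replicates_per_count = as.integer(replicates_per_count),
                 target_cell_area_px = as.integer(target_cell_area_px),
                 rng_seed = as.integer(rng_seed),
                 growth_connectivity = as.integer(growth_connectivity),
                 placement = match.arg(placement)),
            class = "simulation_config")
}

#' Estimate the typical cell area from a segmented red mask
#'
#' Median connected-component pixel area, the quantity "size of the real
#' cells" that the artificial cell growth should match.
#'
#' @param a_r red cell mask.
#' @param connectivity 4 or 8.
#' @return integer pixel area (>= 1), or an error if the mask is empty.
#' @export
estimate_cell_area <- function(a_r, connectivity = 8L) {
  lab <- label_components(a_r, connectivity)
  if (max(lab) == 0L) pv_degenerate_error("red mask has no components")
  max(1L, as.integer(round(median(tabulate(lab, nbins = max(lab))))))
}

#' Grow one artificial cell from a seed pixel
#'
#' Starting from a single seed pixel, one uniformly random unoccupied
#' allowed pixel adjacent to the current blob is added per step until the
#' blob reaches `target_area_px` pixels (or its connected allowed region is
#' exhausted).  The random ragged outline makes the artificial cells
#' morphologically similar to real segmented cells.  Randomness comes from
#' R's global RNG (`set.seed()` applies).
#'
#' @param seed integer `(row, col)`, 1-based, must lie in `allowed`.
#' @param target_area_px target blob area in pixels (>= 1).
#' @param allowed logical mask of pixels the cell may occupy.
#' @param connectivity growth connectivity, 4 (default) or 8.
#' @return logical mask of the grown blob.
#' @export
grow_random_cell <- function(seed, target_area_px, allowed, connectivity = 4L) {
  assert_mask(allowed)
  seed <- as.integer(seed)
  if (length(seed) != 2L || anyNA(seed) ||
      seed[1] < 1L || seed[1] > nrow(allowed) ||
      seed[2] < 1L || seed[2] > ncol(allowed) || !allowed[seed[1], seed[2]])
    pv_validation_error("seed must be an allowed (row, col) pixel")
  if (target_area_px < 1) pv_validation_error("target_area_px must be >= 1")
  cpp_grow_cells(allowed, seed[1] - 1L, seed[2] - 1L,
                 as.integer(target_area_px), as.integer(connectivity))
}

#' Generate one image of randomly distributed artificial cells
#'
#' Two placement modes are offered:
#' * `"overlay"` (the original procedure): `n_seeds` seed points are
#'   scattered uniformly over the whole frame, each grown freely by
#'   [grow_random_cell()] on the frame, and the resulting overlay is
#'   clipped to `a_t` minus `forbidden` — cell parts inside the vessel or
#'   outside the specimen are eliminated.  By translation invariance the
#'   retained cell-pixel density is spatially uniform, which is what makes
#'   this the reference null.
#' * `"constrained"`: seed points are drawn uniformly without replacement
#'   from `a_t` minus `forbidden` and growth itself is confined to that
#'   region, so exactly `n_seeds` cells of (up to) `target_area` pixels
#'   are placed.  Blocked growth folds cell mass back against region
#'   boundaries, so this mode slightly over-represents pixels near the
#'   structure; use it when an exact planted pixel count matters more than
#'   spatial unbiasedness.
#'
#' Blobs are grown independently; overlapping blobs merge in the returned
#' union mask, as real stained areas do.
#'
#' @param a_t specimen mask.
#' @param forbidden mask of pixels cells may not occupy (e.g. A_B).
#' @param n_seeds number of cells.
#' @param target_area target pixel area per cell.
#' @param connectivity growth connectivity (4 or 8).
#' @param mode `"overlay"` or `"constrained"` (default; exact contracts).
#' @return logical mask of the artificial cell pixels, always a subset of
#'   `a_t & !forbidden`.
#' @export
generate_random_cell_image <- function(a_t, forbidden, n_seeds, target_area,
                                       connectivity = 4L,
                                       mode = c("constrained", "overlay")) {
  assert_mask(a_t); assert_mask(forbidden)
  assert_same_shape(a_t, forbidden)
  mode <- match.arg(mode)
  allowed <- a_t & !forbidden
  n_allowed <- sum(allowed)
  if (n_seeds > n_allowed)
    pv_validation_error("infeasible density: %d seeds for %d allowed pixels",
                        n_seeds, n_allowed)
  if (n_seeds == 0L) return(matrix(FALSE, nrow(a_t), ncol(a_t)))
  H <- nrow(a_t)
  if (mode == "constrained") {
    idx <- which(allowed)
    seeds <- idx[sample.int(length(idx), n_seeds)]
    grown <- cpp_grow_cells(allowed, (seeds - 1L) %% H, (seeds - 1L) %/% H,
                            as.integer(target_area), as.integer(connectivity))
    grown
  } else {
    seeds <- sample.int(length(a_t), n_seeds)
    frame <- matrix(TRUE, H, ncol(a_t))
    grown <- cpp_grow_cells(frame, (seeds - 1L) %% H, (seeds - 1L) %/% H,
                            as.integer(target_area), as.integer(connectivity))
    grown & allowed
  }
}

#' Run the random-distribution simulation study
#'
#' For every seed count and replicate, generates one random-cell image on
#' the given sample geometry and computes the density fractions `F_N`,
#' `F_D` at every neighborhood width against the fixed neighborhood
#' geometry of `(structure_b, a_t)`.  Per-replicate RNG streams are derived
#' deterministically from `config$rng_seed`, so any single replicate is
#' reproducible in isolation (see `rep_seed` in the output).
#'
#' @param a_t specimen mask.
#' @param structure_b structure mask A_B (nonempty).
#' @param widths_um neighborhood widths in µm.
#' @param config a [simulation_config()].
#' @param scale scale in px/µm used to convert widths to kernels.
#' @param forbidden mask of pixels cells may not occupy; defaults to
#'   `structure_b` (cells are eliminated inside the vessel).
#' @return an object of class `simulation_study`: list with `config`,
#'   `per_replicate` (data.frame: seed_count, replicate, rep_seed,
#'   width_um, F_N, F_D, ratio) and `summary` (mean and SD of F_N, F_D and
#'   ratio per seed_count x width).
#' @export
run_simulation_study <- function(a_t, structure_b, widths_um = c(10, 20, 30, 40, 50),
                                 config = simulation_config(), scale = 1.5,
                                 forbidden = structure_b) {
  stopifnot(inherits(config, "simulation_config"))
  geoms <- lapply(widths_um, function(w) {
    k <- kernel_px_for_width(w, scale)
    nb <- neighborhood_areas(structure_b, a_t, k)
    list(width = w, idx_n = which(nb$a_n), idx_d = which(nb$a_d),
         n_n = mask_area(nb$a_n), n_d = mask_area(nb$a_d))
  })
  if (any(vapply(geoms, function(g) g$n_n == 0L || g$n_d == 0L, logical(1))))
    pv_degenerate_error("a neighborhood width saturates the specimen (empty A_N or A_D)")
  reps <- expand.grid(replicate = seq_len(config$replicates_per_count),
                      seed_count = config$seed_counts)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)
  rep_seeds <- sample.int(.Machine$integer.max, nrow(reps))
  rows <- vector("list", nrow(reps))
  for (i in seq_len(nrow(reps))) {
    set.seed(rep_seeds[i])
    cells <- generate_random_cell_image(a_t, forbidden, reps$seed_count[i],
                                        config$target_cell_area_px,
                                        config$growth_connectivity,
                                        mode = config$placement)
    per_w <- lapply(geoms, function(g) {
      f_n <- sum(cells[g$idx_n]) / g$n_n
      f_d <- sum(cells[g$idx_d]) / g$n_d
      data.frame(seed_count = reps$seed_count[i], replicate = reps$replicate[i],
                 rep_seed = rep_seeds[i], width_um = g$width,
                 F_N = f_n, F_D = f_d,
                 ratio = if (f_d > 0) f_n / f_d else NA_real_)
    })
    rows[[i]] <- do.call(rbind, per_w)
  }
  per_replicate <- do.call(rbind, rows)
  groups <- split(per_replicate,
                  list(per_replicate$seed_count, per_replicate$width_um),
                  drop = TRUE)
  summary_df <- do.call(rbind, lapply(groups, function(g) data.frame(
    seed_count = g$seed_count[1], width_um = g$width_um[1],
    mean_F_N = mean(g$F_N), sd_F_N = sd(g$F_N),
    mean_F_D = mean(g$F_D), sd_F_D = sd(g$F_D),
    mean_ratio = mean(g$ratio, na.rm = TRUE),
    sd_ratio = sd(g$ratio, na.rm = TRUE))))
  summary_df <- summary_df[order(summary_df$width_um, summary_df$seed_count), ]
  rownames(summary_df) <- NULL
  structure(list(config = config, widths_um = widths_um,
                 per_replicate = per_replicate, summary = summary_df),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("<simulation_study: %d seed counts x %d replicates, widths %s um>\n",
              length(x$config$seed_counts), x$config$replicates_per_count,
              paste(x$widths_um, collapse = ",")))
  print(x$summary)
  invisible(x)
}

#' Write / read the simulation study per-replicate table
#' @param study a `simulation_study`.
#' @param path CSV path.
#' @return `read_simulation_table()` returns a data.frame.
#' @export
write_simulation_table <- function(study, path) {
  stopifnot(inherits(study, "simulation_study"))
  write.csv(study$per_replicate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_simulation_table
#' @export
read_simulation_table <- function(path) {
  if (!file.exists(path)) pv_io_error("cannot read '%s': no such file", path)
  read.csv(path)
}
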