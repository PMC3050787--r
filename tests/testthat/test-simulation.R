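test_that("cell growth honours its size contract and the allowed region", {
  allowed <- matrix(TRUE, 15, 15)
  set.seed(51)
  expect_equal(mask_area(grow_random_cell(c(8, 8), 1, allowed)), 1)
  blob <- grow_random_cell(c(8, 8), 9, allowed)
  expect_equal(mask_area(blob), 9)
  expect_true(blob[8, 8])
  expect_equal(max(label_components(blob, 4)), 1)  # connected

  # region exhaustion: 2x2 allowed island, target 10 -> 4 px
  island <- matrix(FALSE, 10, 10); island[4:5, 4:5] <- TRUE
  grown <- grow_random_cell(c(4, 4), 10, island)
  expect_identical(grown, island)
  expect_error(grow_random_cell(c(1, 1), 5, island),
               class = "perivasc_validation_error")
  # growth never leaves the allowed set
  set.seed(52)
  for (i in 1:20) {
    a <- random_mask(12, 12, 0.6)
    seeds <- which(a, arr.ind = TRUE)
    s <- seeds[sample.int(nrow(seeds), 1), ]
    g <- grow_random_cell(s, 30, a)
    expect_true(all(g <= a))
  }
})

test_that("random cell images have the contracted pixel counts and placement", {
  a_t <- matrix(TRUE, 40, 40)
  forb <- matrix(FALSE, 40, 40); forb[15:25, 15:25] <- TRUE
  set.seed(53)
  expect_equal(mask_area(generate_random_cell_image(a_t, forb, 0, 5)), 0)
  m <- generate_random_cell_image(a_t, forb, 100, 1)
  expect_equal(mask_area(m), 100)       # target 1, seeds distinct
  expect_false(any(m & forb))
  m2 <- generate_random_cell_image(a_t, forb, 30, 12)
  expect_false(any(m2 & forb))
  expect_true(all(m2 <= (a_t & !forb)))
  # overlay mode also confines the retained pixels to the allowed region
  m3 <- generate_random_cell_image(a_t, forb, 60, 15, mode = "overlay")
  expect_true(all(m3 <= (a_t & !forb)))
  expect_error(generate_random_cell_image(forb, a_t, 10, 5),
               class = "perivasc_validation_error")  # infeasible
  # determinism under a fixed seed
  set.seed(99); x1 <- generate_random_cell_image(a_t, forb, 50, 7)
  set.seed(99); x2 <- generate_random_cell_image(a_t, forb, 50, 7)
  expect_identical(x1, x2)
})

test_that("the simulation study keeps its books and is reproducible", {
  fx <- make_fixture(tiny_spec(rng_seed = 55))
  cfg <- simulation_config(seed_counts = c(20L, 40L), replicates_per_count = 1L,
                           target_cell_area_px = 20L, rng_seed = 5L)
  st <- run_simulation_study(fx$truth$a_t, fx$truth$a_b, c(10, 20), cfg, 1.5)
  expect_equal(nrow(st$per_replicate), 2 * 2)      # 2 counts x 1 rep x 2 widths
  expect_equal(sum(st$per_replicate$width_um == 10), 2)
  expect_true(all(st$summary$sd_ratio >= 0 | is.na(st$summary$sd_ratio)))

  st2 <- run_simulation_study(fx$truth$a_t, fx$truth$a_b, c(10, 20), cfg, 1.5)
  expect_identical(st$per_replicate, st2$per_replicate)  # full determinism

  # a single replicate is reproducible in isolation from its rep_seed
  row <- st$per_replicate[st$per_replicate$width_um == 10 &
                          st$per_replicate$seed_count == 40, ]
  set.seed(row$rep_seed)
  cells <- generate_random_cell_image(fx$truth$a_t, fx$truth$a_b, 40, 20,
                                      mode = "overlay")
  nb <- neighborhood_areas(fx$truth$a_b, fx$truth$a_t, 31)
  expect_equal(sum(cells & nb$a_n) / mask_area(nb$a_n), row$F_N)

  expect_error(run_simulation_study(fx$truth$a_t,
                                    matrix(FALSE, 96, 96), 10, cfg, 1.5),
               class = "perivasc_degenerate_error")
})

test_that("estimate_cell_area recovers the planted cell size class", {
  fx <- make_fixture(tiny_spec(n_cells = 8L, cell_area_px = 40L, rng_seed = 56))
  est <- estimate_cell_area(fx$truth$a_r)
  expect_true(est >= 30 && est <= 90)  # merging can only enlarge components
  expect_error(estimate_cell_area(matrix(FALSE, 5, 5)),
               class = "perivasc_degenerate_error")
})

test_that("simulation CSV round-trips", {
  fx <- make_fixture(tiny_spec(rng_seed = 57))
  st <- run_simulation_study(fx$truth$a_t, fx$truth$a_b, 10,
                             simulation_config(seed_counts = 10L,
                                               replicates_per_count = 2L,
                                               target_cell_area_px = 10L), 1.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_simulation_table(st, p)
  back <- read_simulation_table(p)
  expect_equal(back$F_N, st$per_replicate$F_N, tolerance = 1e-12)
})
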