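mk_summaries <- function(f_n, f_d, width = 10) {
  data.frame(patient_id = sprintf("P%02d", seq_along(f_n)), width_um = width,
             median_F_N = f_n, median_F_D = f_d, n_samples = 1L,
             normalized_ratio = ifelse(f_d > 0, f_n / f_d, NA_real_),
             stringsAsFactors = FALSE)
}

test_that("patient summaries are per-patient medians", {
  res <- data.frame(
    image_id = c("a", "b", "c", "d", "e", "f"),
    width_um = 10,
    F_N = c(0.1, 0.3, 0.2, 0.1, 0.2, 0.5),
    F_D = c(0.05, 0.05, 0.05, 0.1, 0.4, 0.5))
  map <- data.frame(image_id = c("a", "b", "c", "d", "e", "f"),
                    patient_id = c("P1", "P1", "P1", "P2", "P2", "P3"))
  s <- summarize_patients(res, map)
  expect_equal(s$median_F_N[s$patient_id == "P1"], 0.2)  # odd count
  expect_equal(s$median_F_N[s$patient_id == "P2"], 0.15) # even count
  expect_equal(s$median_F_N[s$patient_id == "P3"], 0.5)  # identity
  expect_equal(s$n_samples, c(3L, 2L, 1L))
  expect_equal(s$normalized_ratio[s$patient_id == "P1"], 0.2 / 0.05)
  expect_error(summarize_patients(res, map[-1, ]),
               class = "perivasc_validation_error")
})

test_that("the exact paired Wilcoxon matches hand results and enumeration", {
  # all differences zero -> degenerate p = 1
  t0 <- paired_wilcoxon(mk_summaries(rep(0.2, 8), rep(0.2, 8)), 10)
  expect_equal(t0$p_two_tailed, 1)
  expect_false(t0$significant)

  # n = 6, all positive -> two-tailed p = 2/64
  t6 <- paired_wilcoxon(mk_summaries(seq(0.2, 0.7, 0.1), rep(0.1, 6)), 10)
  expect_equal(t6$p_two_tailed, 2 / 64)
  expect_equal(t6$statistic, 21)
  expect_equal(t6$method, "exact")

  # random cohorts n <= 10, including ties and zeros, vs enumeration oracle
  set.seed(61)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    # dyadic grid: 0.5 + d - 0.5 is exact in binary floating point, so the
    # planted ties reach the test intact
    d <- sample(c(-3:3) / 16, n, replace = TRUE)
    s <- mk_summaries(0.5 + d, rep(0.5, n))
    p_pkg <- paired_wilcoxon(s, 10)$p_two_tailed
    expect_equal(p_pkg, oracle_wilcoxon_enum(d), tolerance = 1e-12,
                 label = paste("cohort", i))
  }
})

test_that("the exact test agrees with stats::wilcox.test when ties are absent", {
  set.seed(62)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    f_n <- runif(n); f_d <- runif(n)
    p_pkg <- paired_wilcoxon(mk_summaries(f_n, f_d), 10)$p_two_tailed
    p_ref <- stats::wilcox.test(f_n, f_d, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("large cohorts fall back to the tie-corrected normal approximation", {
  set.seed(63)
  n <- 40
  f_n <- runif(n); f_d <- runif(n)
  t <- paired_wilcoxon(mk_summaries(f_n, f_d), 10)
  expect_equal(t$method, "normal")
  p_ref <- suppressWarnings(
    stats::wilcox.test(f_n, f_d, paired = TRUE, exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(t$p_two_tailed, p_ref, tolerance = 1e-10)
})

test_that("fractions and normalized ratios are invariant under area scaling", {
  # replicating every pixel into a 2x2 block multiplies all areas by 4
  # exactly and must leave F_N, F_D and the ratio unchanged
  set.seed(64)
  a_n <- random_mask(20, 20, 0.3)
  a_d <- !a_n & random_mask(20, 20, 0.9)
  a_r <- random_mask(20, 20, 0.2)
  up <- function(m) matrix(as.logical(kronecker(m, matrix(1, 2, 2))), 40, 40)
  f1 <- density_fractions(a_r, a_n, a_d)
  f2 <- density_fractions(up(a_r), up(a_n), up(a_d))
  expect_equal(f1, f2)

  base <- data.frame(image_id = "a", width_um = 10, F_N = 0.12, F_D = 0.04)
  map <- data.frame(image_id = "a", patient_id = "P1")
  expect_equal(summarize_patients(base, map)$normalized_ratio, 3)
})

test_that("test_all_widths reports every width with optional Holm correction", {
  s <- rbind(mk_summaries(seq(0.2, 0.8, 0.1), rep(0.1, 7), width = 10),
             mk_summaries(rep(0.1, 7), rep(0.1, 7), width = 20))
  tab <- test_all_widths(s, alpha = 0.05)
  expect_equal(tab$width_um, c(10, 20))
  expect_equal(tab$p_two_tailed[2], 1)
  holm <- test_all_widths(s, alpha = 0.05, correct = "holm")
  expect_true(all(holm$p_two_tailed >= tab$p_two_tailed))
})

test_that("QQ data contains patient dots, null points and the reference line", {
  fx <- make_fixture(tiny_spec(rng_seed = 65))
  st <- run_simulation_study(fx$truth$a_t, fx$truth$a_b, 10,
                             simulation_config(seed_counts = c(10L, 20L),
                                               replicates_per_count = 20L,
                                               target_cell_area_px = 20L,
                                               rng_seed = 2L), 1.5)
  s <- mk_summaries(0.1, 0.05)
  qq <- qq_plot_data(s, st, 10)
  expect_equal(sum(qq$kind == "patient"), 1)       # one patient, one dot
  expect_equal(sum(qq$kind == "null_point"), 2)    # one per seed count
  line <- qq[qq$kind == "null_line", ]
  expect_equal(line$y / line$x, 1, tolerance = 0.15) # null realizes F_N ~ F_D
  np <- qq[qq$kind == "null_point", ]
  expect_equal(np$y, np$x, tolerance = 0.2)
  expect_error(qq_plot_data(s, st, 40), class = "perivasc_validation_error")
})
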