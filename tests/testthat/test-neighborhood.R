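test_that("kernel sizes reproduce the printed series and generalize", {
  expect_identical(kernel_px_for_width(10, 1.5), 31L)
  expect_identical(kernel_px_for_width(20, 1.5), 61L)
  expect_identical(kernel_px_for_width(30, 1.5), 91L)
  expect_identical(kernel_px_for_width(10, 0.5), 11L)  # 2*round(5)+1
  expect_identical(kernel_px_for_width(c(10, 20, 30, 40, 50), 1.5),
                   c(31L, 61L, 91L, 121L, 151L))
  expect_error(kernel_px_for_width(0, 1.5), class = "perivasc_validation_error")
  expect_error(kernel_px_for_width(10, -1), class = "perivasc_validation_error")
})

test_that("neighborhood areas handle saturation, unit kernel and frame cover", {
  a_t <- matrix(TRUE, 20, 20)
  nb <- neighborhood_areas(a_t, a_t, 3)          # structure fills the specimen
  expect_equal(mask_area(nb$a_n), 0)
  expect_equal(mask_area(nb$a_d), 0)

  st <- matrix(FALSE, 20, 20); st[8:12, 8:12] <- TRUE
  nb1 <- neighborhood_areas(st, a_t, 1)          # unit kernel
  expect_equal(mask_area(nb1$a_n), 0)
  expect_identical(nb1$a_d, a_t & !st)

  one <- matrix(FALSE, 20, 20); one[10, 10] <- TRUE
  nb31 <- neighborhood_areas(one, a_t, 31)       # kernel covers the frame
  expect_equal(mask_area(nb31$a_d), 0)

  expect_error(neighborhood_areas(matrix(FALSE, 20, 20), a_t, 3),
               class = "perivasc_degenerate_error")
  expect_error(neighborhood_areas(a_t, st, 3),   # structure not within A_T
               class = "perivasc_validation_error")
})

test_that("A_N, A_D, A_B partition A_T exactly at every width", {
  set.seed(31)
  for (i in 1:10) {
    a_t <- random_mask(40, 40, 0.9)
    st <- random_mask(40, 40, 0.05) & a_t
    if (!any(st)) next
    for (k in c(3, 11, 31)) {
      nb <- neighborhood_areas(st, a_t, k)
      expect_equal(mask_area(nb$a_n) + mask_area(nb$a_d) + mask_area(st),
                   mask_area(a_t))
      expect_false(any(nb$a_n & nb$a_d) || any(nb$a_n & st) || any(nb$a_d & st))
    }
  }
})

test_that("areas are monotone in width and red mass is conserved", {
  set.seed(32)
  a_t <- random_mask(48, 48, 0.95)
  st <- matrix(FALSE, 48, 48); st[20:28, 22:26] <- TRUE; st <- st & a_t
  a_r <- random_mask(48, 48, 0.1) & a_t & !st
  prev <- NULL
  for (k in c(5, 11, 21, 41)) {
    nb <- neighborhood_areas(st, a_t, k)
    if (!is.null(prev)) {
      expect_true(all(prev$a_n <= (nb$a_n | st)))  # a_n grows with width
      expect_true(all(nb$a_d <= prev$a_d))         # a_d shrinks with width
    }
    expect_equal(sum(a_r & nb$a_n) + sum(a_r & nb$a_d) + sum(a_r & st),
                 mask_area(a_r))
    prev <- nb
  }
})

test_that("density fractions follow their defining arithmetic", {
  shape <- c(40, 40)
  a_n <- matrix(FALSE, 40, 40); a_n[1:10, 1:10] <- TRUE          # 100 px
  a_d <- matrix(FALSE, 40, 40); a_d[11:35, 1:40] <- TRUE         # 1000 px
  a_r <- matrix(FALSE, 40, 40)
  a_r[1, 1:10] <- TRUE                                           # 10 in A_N
  a_r[11, 1:10] <- TRUE                                          # 10 in A_D
  fr <- density_fractions(a_r, a_n, a_d)
  expect_equal(fr$F_N, 0.10)
  expect_equal(fr$F_D, 0.01)
  expect_equal(fr$F_N / fr$F_D, 10)

  sat <- density_fractions(a_n, a_n, a_d)   # a_r == a_n
  expect_equal(sat$F_N, 1); expect_equal(sat$F_D, 0)
  none <- density_fractions(matrix(FALSE, 40, 40), a_n, a_d)
  expect_equal(none$F_N, 0); expect_equal(none$F_D, 0)

  err <- tryCatch(density_fractions(a_r, matrix(FALSE, 40, 40), a_d),
                  perivasc_degenerate_error = identity)
  expect_s3_class(err, "perivasc_degenerate_error")
  expect_true(err$data$empty[["A_N"]])      # error says which side vanished
})

test_that("analyze_image produces monotone areas and honours planted structure", {
  # default 256x256 frame: the residual area survives even at 50 um
  fx <- make_fixture(fixture_spec(rng_seed = 41))
  res <- analyze_image(fx$image, fx$roi, image_id = "im", patient_id = "P")
  expect_equal(nrow(res), 5)
  expect_true(all(diff(res$area_N) >= 0))
  expect_true(all(diff(res$area_D) <= 0))
  expect_true(all(res$area_N + res$area_D + res$area_B == res$area_T))
  expect_error(analyze_image(fx$image, fx$roi, widths_um = c(20, 10)),
               class = "perivasc_validation_error")

  # all red mass within 10 um of the structure -> F_D = 0 at every width
  a_b <- fx$truth$a_b
  near <- (dilate_mask(a_b, kernel_px_for_width(10, 1.5)) & !a_b) & fx$truth$a_t
  px <- array(0L, dim = c(256, 256, 3))
  cols <- list(c(235L, 225L, 225L), c(200L, 60L, 60L), c(60L, 60L, 200L))
  for (ch in 1:3) {
    plane <- matrix(cols[[1]][ch], 256, 256)
    plane[near] <- cols[[2]][ch]
    plane[a_b] <- cols[[3]][ch]
    px[, , ch] <- plane
  }
  res2 <- analyze_image(color_image(px), fx$roi, image_id = "near")
  expect_true(all(res2$F_D == 0))
  expect_true(all(res2$F_N > 0))
})

test_that("an empty specimen or all-excluding ROI raises a degenerate error", {
  fx <- make_fixture(tiny_spec(rng_seed = 42))
  all_excl <- roi_spec(fx$roi$include, fx$roi$include)
  expect_error(analyze_image(fx$image, all_excl),
               class = "perivasc_degenerate_error")
})
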