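#' Patient-level summarization of density fractions
#'
#' When several tissue samples are available from one patient, the
#' information is summarized by the median of the per-sample density
#' fractions, so that testing rests on one robust observation per patient.
#' The median is the standard order-statistic median (mean of the two
#' middle values for even counts).
#'
#' @param results data.frame of per-image results (see [analyze_image()] /
#'   [read_results_table()]).
#' @param mapping data.frame with columns `image_id`, `patient_id`; every
#'   `image_id` in `results` must appear exactly once.
#' @return data.frame with one row per (patient, width): `patient_id`,
#'   `width_um`, `median_F_N`, `median_F_D`, `n_samples` and
#'   `normalized_ratio = median_F_N / median_F_D` (NA when the latter is
#'   0), the per-patient relative density normalized to residual tissue
#'   density = 1.
#' @export
summarize_patients <- function(results, mapping) {
  if (!all(c("image_id", "F_N", "F_D", "width_um") %in% names(results)))
    pv_validation_error("results lack required columns")
  if (!all(c("image_id", "patient_id") %in% names(mapping)))
    pv_validation_error("mapping needs columns image_id, patient_id")
  if (anyDuplicated(mapping$image_id))
    pv_validation_error("mapping has duplicated image_id entries")
  unmapped <- setdiff(unique(results$image_id), mapping$image_id)
  if (length(unmapped))
    pv_validation_error("image(s) missing from mapping: %s",
                        paste(unmapped, collapse = ", "))
  pid <- mapping$patient_id[match(results$image_id, mapping$image_id)]
  groups <- split(results, list(pid, results$width_um), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    p <- mapping$patient_id[match(g$image_id[1], mapping$image_id)]
    m_n <- median(g$F_N); m_d <- median(g$F_D)
    data.frame(patient_id = as.character(p), width_um = g$width_um[1],
               median_F_N = m_n, median_F_D = m_d, n_samples = nrow(g),
               normalized_ratio = if (m_d > 0) m_n / m_d else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$width_um, out$patient_id), ]
  rownames(out) <- NULL
  out
}

# Exact null distribution of the doubled signed-rank statistic over all
# 2^n sign assignments, by polynomial convolution.  ranks2 are the
# mid-ranks multiplied by 2 so everything is integer even under ties.
signed_rank_exact_dist <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)  # f[w + 1] = #assignments with statistic w
  f[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), f[seq_len(total + 1L - r)])
    f <- f + shifted
  }
  f / 2^length(ranks2)
}

#' Paired Wilcoxon signed-rank test of F_N versus F_D
#'
#' Two-tailed paired signed-rank test of the per-patient median
#' neighborhood density against the residual density at one neighborhood
#' width.  Conventions (classical Wilcoxon): zero differences are dropped
#' before ranking; tied absolute differences share average ranks; the
#' two-tailed p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.  The
#' exact permutation distribution (all `2^n` sign assignments, valid under
#' ties) is used for `n <= exact_max_n` pairs; beyond that the normal
#' approximation with tie correction and continuity correction applies.
#'
#' @param summaries output of [summarize_patients()].
#' @param width neighborhood width (µm) to test.
#' @param alpha significance level (default 0.01).
#' @param exact_max_n largest n for the exact distribution (default 25).
#' @return list of class `perivasc_test` with `width_um`, `n_patients`
#'   (pairs at this width), `n_used` (after dropping zero differences),
#'   `statistic` (W+, sum of positive ranks), `p_two_tailed`,
#'   `significant` (at `alpha`), `method` ("exact" or "normal"), and
#'   `low_power` flag (n_used < 6: the exact two-tailed test cannot reach
#'   p < 0.05).
#' @export
paired_wilcoxon <- function(summaries, width, alpha = 0.01, exact_max_n = 25L) {
  s <- summaries[summaries$width_um == width, ]
  if (nrow(s) == 0L)
    pv_validation_error("no patient summaries at width %s", format(width))
  d <- s$median_F_N - s$median_F_D
  n_patients <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    res <- list(width_um = width, n_patients = n_patients, n_used = 0L,
                statistic = 0, p_two_tailed = 1, significant = FALSE,
                method = "degenerate", low_power = TRUE, alpha = alpha)
    class(res) <- "perivasc_test"
    return(res)
  }
  rk <- rank(abs(d))             # mid-ranks for ties
  w_plus <- sum(rk[d > 0])
  if (n <= exact_max_n) {
    ranks2 <- as.integer(round(2 * rk))
    dist <- signed_rank_exact_dist(ranks2)
    w2 <- as.integer(round(2 * w_plus))
    p_lo <- sum(dist[seq_len(w2 + 1L)])
    p_hi <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  res <- list(width_um = width, n_patients = n_patients, n_used = n,
              statistic = w_plus, p_two_tailed = p,
              significant = p < alpha, method = method,
              low_power = n < 6L, alpha = alpha)
  class(res) <- "perivasc_test"
  res
}

#' @export
print.perivasc_test <- function(x, ...) {
  cat(sprintf(
    "Paired Wilcoxon signed-rank, width %g um: W+ = %g, n = %d (%d used), p = %.4g (%s)%s\n",
    x$width_um, x$statistic, x$n_patients, x$n_used, x$p_two_tailed, x$method,
    if (x$significant) sprintf(" *significant at %g*", x$alpha) else ""))
  invisible(x)
}

#' Test all widths and tabulate
#'
#' Convenience wrapper running [paired_wilcoxon()] at every width present
#' in the summaries.  No multiple-testing correction is applied by default
#' (per-width p-values are reported, matching the original analysis);
#' `correct = "holm"` applies a Holm correction across widths.
#'
#' @param summaries output of [summarize_patients()].
#' @param alpha significance level.
#' @param correct `"none"` (default) or `"holm"`.
#' @return data.frame with one row per width.
#' @export
test_all_widths <- function(summaries, alpha = 0.01,
                            correct = c("none", "holm")) {
  correct <- match.arg(correct)
  widths <- sort(unique(summaries$width_um))
  rows <- lapply(widths, function(w) {
    t <- paired_wilcoxon(summaries, w, alpha)
    data.frame(width_um = w, n_patients = t$n_patients, n_used = t$n_used,
               statistic = t$statistic, p_two_tailed = t$p_two_tailed,
               method = t$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correct == "holm")
    out$p_two_tailed <- stats::p.adjust(out$p_two_tailed, "holm")
  out$significant <- out$p_two_tailed < alpha
  out
}

#' Quantile-quantile data of patient densities against the simulated null
#'
#' Produces the plotting table behind the density QQ display: one dot per
#' patient (x = median neighborhood density F_N, y = median residual
#' density F_D), one point per simulated seed count (means of F_N and F_D
#' with their SDs as bar half-lengths), and the random-distribution
#' reference line through the origin with slope pooled
#' `mean(F_D) / mean(F_N)` across seed counts (the F_N = F_D locus as
#' realized by the simulation).
#'
#' @param summaries output of [summarize_patients()].
#' @param null a `simulation_study` covering `width`.
#' @param width neighborhood width (µm).
#' @return data.frame with columns `kind` (`"patient"`, `"null_point"`,
#'   `"null_line"`), `id`, `x`, `y`, `sd_x`, `sd_y`.
#' @export
qq_plot_data <- function(summaries, null, width) {
  stopifnot(inherits(null, "simulation_study"))
  ns <- null$summary[null$summary$width_um == width, ]
  if (nrow(ns) == 0L)
    pv_validation_error("simulation null does not cover width %s", format(width))
  s <- summaries[summaries$width_um == width, ]
  pts <- if (nrow(s) > 0L)
    data.frame(kind = "patient", id = s$patient_id,
               x = s$median_F_N, y = s$median_F_D,
               sd_x = NA_real_, sd_y = NA_real_, stringsAsFactors = FALSE)
  else NULL
  nullpts <- data.frame(kind = "null_point", id = as.character(ns$seed_count),
                        x = ns$mean_F_N, y = ns$mean_F_D,
                        sd_x = ns$sd_F_N, sd_y = ns$sd_F_D,
                        stringsAsFactors = FALSE)
  slope <- mean(ns$mean_F_D) / mean(ns$mean_F_N)
  line <- data.frame(kind = "null_line", id = "slope",
                     x = 1, y = slope, sd_x = NA_real_, sd_y = NA_real_,
                     stringsAsFactors = FALSE)
  out <- rbind(pts, nullpts, line)
  rownames(out) <- NULL
  out
}
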