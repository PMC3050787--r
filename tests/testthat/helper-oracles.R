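# Independent brute-force oracles used to check the package's operations.
# These deliberately take different algorithmic routes from the
# implementation (set algebra / exhaustive enumeration / per-pixel loops).

# dilation as an explicit Minkowski union of shifted copies
oracle_dilate_shift <- function(mask, k) {
  r <- (k - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  for (dr in -r:r) for (dc in -r:r) {
    rows_to <- max(1, 1 + dr):min(H, H + dr)
    cols_to <- max(1, 1 + dc):min(W, W + dc)
    out[rows_to, cols_to] <- out[rows_to, cols_to] |
      mask[rows_to - dr, cols_to - dc]
  }
  out
}

# dilation as Chebyshev-distance thresholding: TRUE iff the L-inf distance
# to the nearest TRUE pixel is <= (k-1)/2
oracle_dilate_chebyshev <- function(mask, k) {
  r <- (k - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, H, W)
  if (nrow(pts) == 0L) return(out)
  pr <- matrix(seq_len(H), H, W)
  pc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dmin <- matrix(Inf, H, W)
  for (i in seq_len(nrow(pts)))
    dmin <- pmin(dmin, pmax(abs(pr - pts[i, 1]), abs(pc - pts[i, 2])))
  dmin <= r
}

# erosion with TRUE padding (the package's documented convention: erosion
# pads TRUE so closing cannot eat objects at the frame border)
oracle_erode_shift <- function(mask, k) {
  r <- (k - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(TRUE, H, W)
  for (dr in -r:r) for (dc in -r:r) {
    shifted <- matrix(TRUE, H, W)  # outside the frame counts as TRUE
    rows_to <- max(1, 1 - dr):min(H, H - dr)
    cols_to <- max(1, 1 - dc):min(W, W - dc)
    shifted[rows_to, cols_to] <- mask[rows_to + dr, cols_to + dc]
    out <- out & shifted
  }
  out
}

# per-pixel loop applying the relative-RGB rule directly
oracle_segment_rule <- function(pixels, target, t, a_t) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    R <- pixels[i, j, 1]; G <- pixels[i, j, 2]; B <- pixels[i, j, 3]
    hit <- if (target == "red") R >= t * G && R >= t * B
           else B >= t * G && B >= t * R
    out[i, j] <- hit && a_t[i, j]
  }
  out
}

# exact two-tailed signed-rank p-value by enumerating all 2^n sign
# assignments of the (tie-averaged) ranks
oracle_wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

random_mask <- function(H, W, density = 0.15) {
  matrix(runif(H * W) < density, H, W)
}

# small, fast fixture used across tests (scaled-down frame; ring vessel);
# any fixture_spec() argument can be overridden
tiny_spec <- function(...) {
  args <- list(frame = c(96L, 96L),
               structure = list(type = "ring", radius_px = 20,
                                thickness_px = 5),
               n_cells = 10L, cell_area_px = 40L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fixture_spec, args)
}
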