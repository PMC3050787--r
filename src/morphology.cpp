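#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// Binary morphology with solid square structuring elements, connected
// component labeling, and the stochastic cell-growth process used by the
// random-distribution null model.  Masks are logical H x W matrices in
// column-major order; the image border behaves as if padded with FALSE.

// sliding-window OR along one dimension via prefix counts: out[i] is TRUE
// iff any TRUE within radius r.  Works on a strided view of the matrix.
static void window_or_1d(const int *in, int *out, int n, int stride, int r) {
  // prefix[i] = number of TRUE among elements 0..i-1
  std::vector<int> prefix(n + 1, 0);
  for (int i = 0; i < n; ++i) prefix[i + 1] = prefix[i] + (in[i * stride] != 0);
  for (int i = 0; i < n; ++i) {
    int lo = i - r < 0 ? 0 : i - r;
    int hi = i + r + 1 > n ? n : i + r + 1;
    out[i * stride] = (prefix[hi] - prefix[lo]) > 0;
  }
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate_square(const LogicalMatrix &mask, int kernel_px) {
  if (kernel_px < 1 || kernel_px % 2 == 0)
    stop("kernel_px must be an odd positive integer");
  int H = mask.nrow(), W = mask.ncol(), r = (kernel_px - 1) / 2;
  LogicalMatrix tmp(H, W), out(H, W);
  if (r == 0) { std::copy(mask.begin(), mask.end(), out.begin()); return out; }
  // columns first (stride 1 within a column), then rows
  for (int j = 0; j < W; ++j)
    window_or_1d(&mask[0] + (R_xlen_t)j * H, &tmp[0] + (R_xlen_t)j * H, H, 1, r);
  for (int i = 0; i < H; ++i)
    window_or_1d(&tmp[0] + i, &out[0] + i, W, H, r);
  return out;
}

// rectangular kernel: kh rows x kw cols, both odd (used by the disk SE,
// which is assembled as a union of row-strips)
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_rect(const LogicalMatrix &mask, int kh, int kw) {
  if (kh < 1 || kh % 2 == 0 || kw < 1 || kw % 2 == 0)
    stop("kernel sides must be odd positive integers");
  int H = mask.nrow(), W = mask.ncol();
  int rh = (kh - 1) / 2, rw = (kw - 1) / 2;
  LogicalMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    window_or_1d(&mask[0] + (R_xlen_t)j * H, &tmp[0] + (R_xlen_t)j * H, H, 1, rh);
  for (int i = 0; i < H; ++i)
    window_or_1d(&tmp[0] + i, &out[0] + i, W, H, rw);
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode_square(const LogicalMatrix &mask, int kernel_px) {
  if (kernel_px < 1 || kernel_px % 2 == 0)
    stop("kernel_px must be an odd positive integer");
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix inv(H, W);
  for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) inv[k] = !mask[k];
  LogicalMatrix d = cpp_dilate_square(inv, kernel_px);
  LogicalMatrix out(H, W);
  for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) out[k] = !d[k];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix &mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  int nn = connectivity;
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) for (int i = 0; i < H; ++i) {
    if (!mask(i, j) || lab(i, j)) continue;
    lab(i, j) = ++next;
    q.clear();
    q.push_back(std::make_pair(i, j));
    while (!q.empty()) {
      std::pair<int, int> p = q.front(); q.pop_front();
      for (int k = 0; k < nn; ++k) {
        int ri = p.first + dr[k], cj = p.second + dc[k];
        if (ri < 0 || ri >= H || cj < 0 || cj >= W) continue;
        if (mask(ri, cj) && !lab(ri, cj)) {
          lab(ri, cj) = next;
          q.push_back(std::make_pair(ri, cj));
        }
      }
    }
  }
  return lab;
}

// Grow blobs from seed pixels.  Each blob starts at its seed and is enlarged
// one pixel at a time: a uniformly random member of the set of unoccupied
// allowed pixels adjacent (4- or 8-connectivity) to the current blob is added
// until the blob has target_area pixels or its connected allowed region is
// exhausted.  Blobs are grown independently (occupancy is per-blob); the
// returned mask is their union, so overlapping blobs merge.  Randomness comes
// from R's RNG (caller manages set.seed).
//
// seeds are 0-based (row, col).
// [[Rcpp::export]]
LogicalMatrix cpp_grow_cells(const LogicalMatrix &allowed,
                             const IntegerVector &seed_row,
                             const IntegerVector &seed_col,
                             int target_area, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  if (target_area < 1) stop("target_area must be >= 1");
  int H = allowed.nrow(), W = allowed.ncol();
  int n = seed_row.size();
  if (seed_col.size() != n) stop("seed_row and seed_col lengths differ");
  LogicalMatrix out(H, W);
  std::fill(out.begin(), out.end(), 0);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  int nn = connectivity;

  // per-blob state, reset lazily via an epoch stamp
  std::vector<int> epoch((size_t)H * W, -1);   // last blob that touched the px
  std::vector<signed char> state((size_t)H * W, 0); // 1 = in blob, 2 = frontier
  std::vector<int> frontier;                   // linear indices of candidates
  std::vector<int> frontier_pos((size_t)H * W, 0);

  RNGScope scope;
  for (int b = 0; b < n; ++b) {
    int sr = seed_row[b], sc = seed_col[b];
    if (sr < 0 || sr >= H || sc < 0 || sc >= W || !allowed(sr, sc))
      stop("seed %d outside the allowed region", b + 1);
    frontier.clear();
    size_t sidx = (size_t)sr + (size_t)sc * H;
    epoch[sidx] = b; state[sidx] = 1;
    out[sidx] = 1;
    int area = 1;
    int cr = sr, cc = sc; // most recently added pixel
    while (area < target_area) {
      // push unoccupied allowed neighbors of the newly added pixel
      for (int k = 0; k < nn; ++k) {
        int ri = cr + dr[k], cj = cc + dc[k];
        if (ri < 0 || ri >= H || cj < 0 || cj >= W) continue;
        if (!allowed(ri, cj)) continue;
        size_t idx = (size_t)ri + (size_t)cj * H;
        if (epoch[idx] == b && state[idx] != 0) continue; // in blob or queued
        epoch[idx] = b; state[idx] = 2;
        frontier_pos[idx] = (int)frontier.size();
        frontier.push_back((int)idx);
      }
      if (frontier.empty()) break; // connected allowed region exhausted
      int pick = (int)(unif_rand() * frontier.size());
      if (pick >= (int)frontier.size()) pick = (int)frontier.size() - 1;
      int idx = frontier[pick];
      // remove from frontier by swap-with-last
      frontier[pick] = frontier.back();
      frontier_pos[(size_t)frontier[pick]] = pick;
      frontier.pop_back();
      state[(size_t)idx] = 1;
      out[idx] = 1;
      ++area;
      cr = idx % H; cc = idx / H;
    }
  }
  return out;
}
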