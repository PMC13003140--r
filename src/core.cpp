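#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Mean distance to the k nearest bank vectors for each query row.
// Distances are plain Euclidean; k = 1 reduces to 1-NN distance.
// [[Rcpp::export]]
NumericVector nn_scores_cpp(NumericMatrix query, NumericMatrix bank, int k) {
  const int q = query.nrow(), n = bank.nrow(), d = query.ncol();
  if (bank.ncol() != d) stop("feature dimension mismatch");
  if (k < 1) stop("k must be >= 1");
  if (k > n) k = n;
  NumericVector out(q);
  // repack both matrices row-major so the inner loop is contiguous
  std::vector<double> B((size_t)n * d), Q((size_t)q * d);
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < d; ++c) B[(size_t)j * d + c] = bank(j, c);
  for (int i = 0; i < q; ++i)
    for (int c = 0; c < d; ++c) Q[(size_t)i * d + c] = query(i, c);
  std::vector<double> d2(n);
  for (int i = 0; i < q; ++i) {
    const double *qi = &Q[(size_t)i * d];
    for (int j = 0; j < n; ++j) {
      const double *bj = &B[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = qi[c] - bj[c];
        s += diff * diff;
      }
      d2[j] = s;
    }
    if (k == 1) {
      out[i] = std::sqrt(*std::min_element(d2.begin(), d2.end()));
    } else {
      std::partial_sort(d2.begin(), d2.begin() + k, d2.end());
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += std::sqrt(d2[j]);
      out[i] = acc / k;
    }
  }
  return out;
}

// Greedy k-center (farthest-point) subsampling. `start` is a 1-based row
// index; each subsequent pick is the row with the largest distance to the
// current selection. Ties resolve to the lowest row index (std::max on >).
// [[Rcpp::export]]
IntegerVector greedy_coreset_cpp(NumericMatrix x, int n_select, int start) {
  const int m = x.nrow(), d = x.ncol();
  if (start < 1 || start > m) stop("start index out of range");
  if (n_select < 1 || n_select > m) stop("invalid selection size");
  IntegerVector sel(n_select);
  std::vector<double> X((size_t)m * d);
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < d; ++c) X[(size_t)j * d + c] = x(j, c);
  std::vector<double> mind(m, R_PosInf);
  int cur = start - 1;
  sel[0] = start;
  for (int it = 1; it < n_select; ++it) {
    int best = -1;
    double bestd = -1.0;
    const double *xc = &X[(size_t)cur * d];
    for (int j = 0; j < m; ++j) {
      const double *xj = &X[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = xj[c] - xc[c];
        s += diff * diff;
      }
      if (s < mind[j]) mind[j] = s;
      if (mind[j] > bestd) { bestd = mind[j]; best = j; }
    }
    cur = best;
    sel[it] = best + 1;
  }
  return sel;
}

// Connected-component labeling of a binary mask with 4- or 8-connectivity.
// Components are numbered 1..n in row-major order of first encounter.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int t = 0; t < nn; ++t) {
          int rr = p.first + dr[t], cc = p.second + dc[t];
          if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Seeded region growing: 4-connected flood fill over the pixels whose value
// differs from the seed value by at most `tol` (Euclidean over channels).
// `img` is an H x W x C array flattened column-major; seed is 0-based.
// [[Rcpp::export]]
LogicalMatrix region_grow_cpp(NumericVector img, int h, int w, int nc,
                              int seed_r, int seed_c, double tol) {
  if (seed_r < 0 || seed_r >= h || seed_c < 0 || seed_c >= w)
    stop("seed outside image");
  if (tol < 0) stop("tolerance must be non-negative");
  LogicalMatrix out(h, w);
  std::vector<double> seedv(nc);
  const R_xlen_t plane = (R_xlen_t)h * w;
  for (int c = 0; c < nc; ++c)
    seedv[c] = img[(R_xlen_t)c * plane + (R_xlen_t)seed_c * h + seed_r];
  const double tol2 = tol * tol;
  const int dr[] = {-1, 1, 0, 0}, dc[] = {0, 0, -1, 1};
  std::queue<std::pair<int, int> > q;
  out(seed_r, seed_c) = true;
  q.push(std::make_pair(seed_r, seed_c));
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int t = 0; t < 4; ++t) {
      int rr = p.first + dr[t], cc = p.second + dc[t];
      if (rr < 0 || rr >= h || cc < 0 || cc >= w || out(rr, cc)) continue;
      double s = 0.0;
      for (int c = 0; c < nc; ++c) {
        double diff = img[(R_xlen_t)c * plane + (R_xlen_t)cc * h + rr] - seedv[c];
        s += diff * diff;
      }
      if (s <= tol2) {
        out(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  return out;
}
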