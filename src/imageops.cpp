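// Low-level raster operations for two-channel fluorescence field analysis.
// All matrices are R column-major; (row, col) indexing is 1-based on the R
// side and converted here. Boundary handling: convolution reflects, running
// morphology replicates edge values.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---- separable convolution (reflect boundary) ------------------------------

static void conv1d_cols(const NumericMatrix& src, NumericMatrix& dst,
                        const NumericVector& k) {
  const int nr = src.nrow(), nc = src.ncol();
  const int kl = k.size(), half = kl / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kl; ++t) {
        int ii = i + t - half;
        if (ii < 0) ii = -ii - 1;             // reflect
        if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += src(ii, j) * k[t];
      }
      dst(i, j) = acc;
    }
  }
}

static void conv1d_rows(const NumericMatrix& src, NumericMatrix& dst,
                        const NumericVector& k) {
  const int nr = src.nrow(), nc = src.ncol();
  const int kl = k.size(), half = kl / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kl; ++t) {
        int jj = j + t - half;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        acc += src(i, jj) * k[t];
      }
      dst(i, j) = acc;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(NumericMatrix img, NumericVector kernel) {
  NumericMatrix tmp(img.nrow(), img.ncol());
  NumericMatrix out(img.nrow(), img.ncol());
  conv1d_cols(img, tmp, kernel);
  conv1d_rows(tmp, out, kernel);
  return out;
}

// ---- running min/max (grayscale erosion/dilation, rectangular SE) ----------

// Monotonic-deque sliding window over one line; window = 2*half+1, edge
// replicated. op: true = max, false = min.
static void run_line(const double* x, double* y, int n, int half, bool mx) {
  std::deque<int> dq;
  for (int i = 0; i < n + half; ++i) {
    int idx = i < n ? i : n - 1;           // replicate right edge
    double v = x[idx];
    while (!dq.empty()) {
      double back = x[dq.back() < n ? dq.back() : n - 1];
      if (mx ? (back <= v) : (back >= v)) dq.pop_back(); else break;
    }
    dq.push_back(i);
    int out = i - half;
    if (out >= 0) {
      while (dq.front() < out - half) dq.pop_front();
      int fi = dq.front(); if (fi >= n) fi = n - 1;
      y[out] = x[fi];
    }
  }
}

static NumericMatrix morph_rect(const NumericMatrix& img, int half, bool mx) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  std::vector<double> buf(std::max(nr, nc)), res(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {           // columns first
    for (int i = 0; i < nr; ++i) buf[i] = img(i, j);
    run_line(buf.data(), res.data(), nr, half, mx);
    for (int i = 0; i < nr; ++i) tmp(i, j) = res[i];
  }
  for (int i = 0; i < nr; ++i) {           // then rows
    for (int j = 0; j < nc; ++j) buf[j] = tmp(i, j);
    run_line(buf.data(), res.data(), nc, half, mx);
    for (int j = 0; j < nc; ++j) out(i, j) = res[j];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode_rect(NumericMatrix img, int half_width) {
  return morph_rect(img, half_width, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_rect(NumericMatrix img, int half_width) {
  return morph_rect(img, half_width, true);
}

// ---- connected components (8-connectivity) ---------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < 8; ++t) {
          int qi = pi + dr[t], qj = pj + dc[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---- hole filling -----------------------------------------------------------

// Background (4-connected) not reachable from the border is a hole; holes are
// set to foreground.

// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix reach(nr, nc);
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    if (!mask(0, j)) { reach(0, j) = true; stack.push_back(0 + j * nr); }
    if (!mask(nr - 1, j) && !reach(nr - 1, j)) {
      reach(nr - 1, j) = true; stack.push_back(nr - 1 + j * nr);
    }
  }
  for (int i = 0; i < nr; ++i) {
    if (!mask(i, 0) && !reach(i, 0)) { reach(i, 0) = true; stack.push_back(i); }
    if (!mask(i, nc - 1) && !reach(i, nc - 1)) {
      reach(i, nc - 1) = true; stack.push_back(i + (nc - 1) * nr);
    }
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int pi = p % nr, pj = p / nr;
    for (int t = 0; t < 4; ++t) {
      int qi = pi + dr[t], qj = pj + dc[t];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (!mask(qi, qj) && !reach(qi, qj)) {
        reach(qi, qj) = true;
        stack.push_back(qi + qj * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !reach(i, j);
  return out;
}

// ---- exact disk dilation of a binary mask ----------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(LogicalMatrix mask, int radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  // precompute disk offsets
  std::vector<std::pair<int, int> > off;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) off.push_back(std::make_pair(a, b));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      for (size_t t = 0; t < off.size(); ++t) {
        int qi = i + off[t].first, qj = j + off[t].second;
        if (qi >= 0 && qi < nr && qj >= 0 && qj < nc) out(qi, qj) = true;
      }
    }
  }
  return out;
}

// ---- distance transform (chamfer 3-4, scaled to ~pixels) -------------------

// [[Rcpp::export]]
NumericMatrix cpp_dist_transform(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e12;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;
  // forward pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i > 0)            v = std::min(v, d(i - 1, j) + 3.0);
      if (j > 0)            v = std::min(v, d(i, j - 1) + 3.0);
      if (i > 0 && j > 0)   v = std::min(v, d(i - 1, j - 1) + 4.0);
      if (i < nr - 1 && j > 0) v = std::min(v, d(i + 1, j - 1) + 4.0);
      d(i, j) = v;
    }
  }
  // backward pass
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      double v = d(i, j);
      if (i < nr - 1)             v = std::min(v, d(i + 1, j) + 3.0);
      if (j < nc - 1)             v = std::min(v, d(i, j + 1) + 3.0);
      if (i < nr - 1 && j < nc - 1) v = std::min(v, d(i + 1, j + 1) + 4.0);
      if (i > 0 && j < nc - 1)    v = std::min(v, d(i - 1, j + 1) + 4.0);
      d(i, j) = v;
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) /= 3.0;
  return d;
}

// ---- marker-based watershed (priority flood) --------------------------------

struct WsNode {
  double prio; long order; int idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // lower priority first
    return a.order > b.order;                       // FIFO tie-break
  }
};

// Floods `mask` from labeled `markers`, ascending `priority` (use -distance
// to grow from object centers). Returns a full labeling of mask pixels.

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers,
                            LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long counter = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        WsNode n = {priority(i, j), counter++, i + j * nr};
        pq.push(n);
      }
  while (!pq.empty()) {
    WsNode n = pq.top(); pq.pop();
    int pi = n.idx % nr, pj = n.idx / nr;
    int l = lab(pi, pj);
    for (int t = 0; t < 4; ++t) {
      int qi = pi + dr[t], qj = pj + dc[t];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (mask(qi, qj) && lab(qi, qj) == 0) {
        lab(qi, qj) = l;
        WsNode m = {priority(qi, qj), counter++, qi + qj * nr};
        pq.push(m);
      }
    }
  }
  return lab;
}
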