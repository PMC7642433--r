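// Low-level raster operations for the digital-pathology module: exact
// Euclidean distance transform (Felzenszwalb & Huttenlocher lower-envelope
// algorithm), 8-connected component labeling, square-window maximum filter,
// and marker-controlled watershed by priority flooding.
//
// Images are R matrices (column-major); pixel (r, c) is element r + c*nr.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of a sampled function f.
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

}  // namespace

// Euclidean distance from every pixel to the nearest TRUE pixel.
// [[Rcpp::export]]
NumericMatrix edt_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  // large finite stand-in for infinity: INF would give NaN in the
  // envelope intersections when two unseen parabolas meet
  const double LARGE = 1e20;
  std::vector<double> g(nr * nc);
  for (int i = 0; i < nr * nc; ++i) g[i] = mask[i] ? 0.0 : LARGE;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = g[r + c * nr];
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g[r + c * nr] = d[r];
  }
  // rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g[r + c * nr];
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out[r + c * nr] = std::sqrt(d[c]);
  }
  return out;
}

// 8-connected component labeling of a binary mask (labels 1..K in scan
// order of first pixel encountered).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int p = r + c * nr;
      if (!mask[p] || lab[p]) continue;
      ++next;
      stack.push_back(p);
      lab[p] = next;
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        int qr = q % nr, qc = q / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = qr + dr, cc = qc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int pp = rr + cc * nr;
            if (mask[pp] && !lab[pp]) {
              lab[pp] = next;
              stack.push_back(pp);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Square-window maximum filter with half-width `radius` pixels.
// [[Rcpp::export]]
NumericMatrix max_filter_cpp(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = -INF;
      for (int rr = std::max(0, r - radius);
           rr <= std::min(nr - 1, r + radius); ++rr) {
        m = std::max(m, img(rr, c));
      }
      tmp(r, c) = m;
    }
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double m = -INF;
      for (int cc = std::max(0, c - radius);
           cc <= std::min(nc - 1, c + radius); ++cc) {
        m = std::max(m, tmp(r, cc));
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Square-window mean filter with half-width `radius` pixels (separable,
// cumulative sums; window clipped at the borders).
// [[Rcpp::export]]
NumericMatrix mean_filter_cpp(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  std::vector<double> cs;
  for (int c = 0; c < nc; ++c) {
    cs.assign(nr + 1, 0.0);
    for (int r = 0; r < nr; ++r) cs[r + 1] = cs[r] + img(r, c);
    for (int r = 0; r < nr; ++r) {
      int lo = std::max(0, r - radius), hi = std::min(nr - 1, r + radius);
      tmp(r, c) = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
  for (int r = 0; r < nr; ++r) {
    cs.assign(nc + 1, 0.0);
    for (int c = 0; c < nc; ++c) cs[c + 1] = cs[c] + tmp(r, c);
    for (int c = 0; c < nc; ++c) {
      int lo = std::max(0, c - radius), hi = std::min(nc - 1, c + radius);
      out(r, c) = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
  return out;
}

// Marker-controlled watershed: flood `mask` from labeled `markers`,
// processing pixels in order of decreasing `elevation` (here: the distance
// transform), FIFO within ties for determinism.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(LogicalMatrix mask, NumericMatrix elevation,
                            IntegerMatrix markers) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  struct Item {
    double elev;
    long order;
    int pix, label;
  };
  struct Cmp {
    bool operator()(const Item& a, const Item& b) const {
      if (a.elev != b.elev) return a.elev < b.elev;  // max-heap on elevation
      return a.order > b.order;                      // FIFO within ties
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  long counter = 0;
  for (int p = 0; p < nr * nc; ++p) {
    if (markers[p] > 0 && mask[p]) {
      pq.push({elevation[p], counter++, p, markers[p]});
    }
  }
  while (!pq.empty()) {
    Item it = pq.top();
    pq.pop();
    if (lab[it.pix]) continue;
    lab[it.pix] = it.label;
    int qr = it.pix % nr, qc = it.pix / nr;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int rr = qr + dr, cc = qc + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int pp = rr + cc * nr;
        if (mask[pp] && !lab[pp]) {
          pq.push({elevation[pp], counter++, pp, it.label});
        }
      }
    }
  }
  return lab;
}
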