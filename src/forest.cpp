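// Per-gene random-forest regression with OOB permutation importance.
//
// Each gene's expression is regressed on the two polar CD8 metrics (R,
// theta). Both predictors are candidates at every split (no predictor
// subsampling); patients are bootstrap-resampled per tree. Importance for a
// predictor is the mean over trees of the increase in out-of-bag MSE when
// that predictor's OOB values are permuted, expressed as a percentage of
// the forest's aggregated OOB MSE.
//
// All randomness comes from R's RNG (unif_rand), so results are
// reproducible under set.seed() and single-threaded evaluation.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat;      // -1 for leaf
  double thr;
  double pred;
  int left, right;
};

// Sample indices are kept in two parallel buffers, each sorted by one
// feature; a split stable-partitions both buffers, so children stay sorted
// and no per-node sorting is needed.
struct TreeBuilder {
  const double* y;
  const double* x[2];
  const double* w;
  int min_node;
  std::vector<Node> nodes;
  std::vector<int> ord[2];   // in-bag indices sorted by feature
  std::vector<int> scratch;

  int build(int lo, int hi) {
    double sw = 0, swy = 0;
    for (int p = lo; p < hi; ++p) {
      int i = ord[0][p];
      sw += w[i];
      swy += w[i] * y[i];
    }
    Node nd;
    nd.feat = -1;
    nd.thr = 0;
    nd.pred = swy / sw;
    nd.left = nd.right = -1;

    double best_score = 1e-12;  // maximize swyL^2/swL + swyR^2/swR - base
    int best_f = -1;
    double best_thr = 0;
    if (sw > min_node) {
      double base = swy * swy / sw;
      for (int f = 0; f < 2; ++f) {
        const double* xf = x[f];
        const std::vector<int>& of = ord[f];
        double wl = 0, wyl = 0;
        for (int p = lo; p + 1 < hi; ++p) {
          int i = of[p];
          wl += w[i];
          wyl += w[i] * y[i];
          if (xf[i] == xf[of[p + 1]]) continue;
          double wr = sw - wl, wyr = swy - wyl;
          if (wl < 1 || wr < 1) continue;
          double score = wyl * wyl / wl + wyr * wyr / wr - base;
          if (score > best_score) {
            best_score = score;
            best_f = f;
            best_thr = 0.5 * (xf[i] + xf[of[p + 1]]);
          }
        }
      }
    }
    if (best_f < 0) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    // stable partition both orderings on the chosen split
    int mid = lo;
    for (int f = 0; f < 2; ++f) {
      std::vector<int>& of = ord[f];
      int nl = 0, nr = 0;
      for (int p = lo; p < hi; ++p) {
        int i = of[p];
        if (x[best_f][i] <= best_thr) {
          of[lo + nl++] = i;
        } else {
          scratch[nr++] = i;
        }
      }
      for (int q = 0; q < nr; ++q) of[lo + nl + q] = scratch[q];
      mid = lo + nl;
    }
    nd.feat = best_f;
    nd.thr = best_thr;
    int self = (int)nodes.size();
    nodes.push_back(nd);
    nodes[self].left = build(lo, mid);
    nodes[self].right = build(mid, hi);
    return self;
  }

  double predict(double x1, double x2) const {
    double xv[2] = {x1, x2};
    int cur = 0;
    while (nodes[cur].feat >= 0) {
      cur = (xv[nodes[cur].feat] <= nodes[cur].thr) ? nodes[cur].left
                                                    : nodes[cur].right;
    }
    return nodes[cur].pred;
  }
};

void shuffle_inplace(std::vector<double>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

}  // namespace

// [[Rcpp::export]]
List rf_importance_cpp(NumericMatrix Y, NumericVector x1, NumericVector x2,
                       int n_trees, int min_node) {
  const int n = x1.size();
  const int n_genes = Y.nrow();
  NumericVector oob_mse(n_genes), inc1(n_genes), inc2(n_genes);
  LogicalVector constant(n_genes);

  std::vector<double> yg(n);
  const double* xs[2];
  std::vector<double> xv1(x1.begin(), x1.end()), xv2(x2.begin(), x2.end());
  xs[0] = xv1.data();
  xs[1] = xv2.data();

  // global sample order by each feature (shared by every gene and tree)
  std::vector<int> gorder[2];
  for (int f = 0; f < 2; ++f) {
    gorder[f].resize(n);
    for (int i = 0; i < n; ++i) gorder[f][i] = i;
    const double* xf = xs[f];
    std::stable_sort(gorder[f].begin(), gorder[f].end(),
                     [xf](int a, int b) { return xf[a] < xf[b]; });
  }

  for (int g = 0; g < n_genes; ++g) {
    for (int i = 0; i < n; ++i) yg[i] = Y(g, i);
    double mn = yg[0], mx = yg[0];
    for (int i = 1; i < n; ++i) { mn = std::min(mn, yg[i]); mx = std::max(mx, yg[i]); }
    if (mx - mn <= 0) {  // constant response: importances defined as 0
      constant[g] = true;
      continue;
    }

    std::vector<double> sum_pred(n, 0.0);
    std::vector<int> cnt_pred(n, 0);
    double d1 = 0, d2 = 0;  // sums of per-tree MSE differences
    int used_trees = 0;

    for (int t = 0; t < n_trees; ++t) {
      std::vector<double> w(n, 0.0);
      for (int i = 0; i < n; ++i) {
        int j = (int)std::floor(unif_rand() * n);
        if (j >= n) j = n - 1;
        w[j] += 1.0;
      }
      std::vector<int> inbag, oob;
      for (int i = 0; i < n; ++i) (w[i] > 0 ? inbag : oob).push_back(i);
      if (oob.empty()) continue;

      TreeBuilder tb;
      tb.y = yg.data();
      tb.x[0] = xs[0];
      tb.x[1] = xs[1];
      tb.w = w.data();
      tb.min_node = min_node;
      tb.nodes.reserve(64);
      tb.scratch.resize(inbag.size());
      for (int f = 0; f < 2; ++f) {
        tb.ord[f].reserve(inbag.size());
        for (int i : gorder[f]) if (w[i] > 0) tb.ord[f].push_back(i);
      }
      tb.build(0, (int)inbag.size());

      double mse0 = 0;
      for (int i : oob) {
        double p = tb.predict(xs[0][i], xs[1][i]);
        sum_pred[i] += p;
        cnt_pred[i] += 1;
        mse0 += (yg[i] - p) * (yg[i] - p);
      }
      mse0 /= oob.size();

      for (int f = 0; f < 2; ++f) {
        std::vector<double> perm(oob.size());
        for (size_t k = 0; k < oob.size(); ++k) perm[k] = xs[f][oob[k]];
        shuffle_inplace(perm);
        double msep = 0;
        for (size_t k = 0; k < oob.size(); ++k) {
          int i = oob[k];
          double p = (f == 0) ? tb.predict(perm[k], xs[1][i])
                              : tb.predict(xs[0][i], perm[k]);
          msep += (yg[i] - p) * (yg[i] - p);
        }
        msep /= oob.size();
        (f == 0 ? d1 : d2) += msep - mse0;
      }
      ++used_trees;
    }

    double agg = 0;
    int m = 0;
    for (int i = 0; i < n; ++i) {
      if (cnt_pred[i] > 0) {
        double e = yg[i] - sum_pred[i] / cnt_pred[i];
        agg += e * e;
        ++m;
      }
    }
    agg = (m > 0) ? agg / m : 0.0;
    oob_mse[g] = agg;
    if (used_trees > 0 && agg > 0) {
      inc1[g] = 100.0 * (d1 / used_trees) / agg;
      inc2[g] = 100.0 * (d2 / used_trees) / agg;
    }
  }

  return List::create(_["oob_mse"] = oob_mse, _["inc_mse_1"] = inc1,
                      _["inc_mse_2"] = inc2, _["constant"] = constant);
}
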