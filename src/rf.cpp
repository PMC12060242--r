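// Bootstrap-aggregated regression trees with variance-reduction splits.
//
// Trees are grown to purity (min split size 2, min leaf 1) on bootstrap
// samples; `mtry` features are drawn without replacement at every node and
// the split maximising the SSE reduction
//   gain = SSE(node) - SSE(left) - SSE(right)
// is taken (strict improvement required, first best wins, so the build is
// deterministic under R's RNG). Per-feature impurity importance accumulates
// the same gains over all splits of all trees. Randomness comes from R's
// RNG so forests are reproducible via set.seed().

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
};

static int grow(const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int lo, int hi, int mtry,
                Tree& tr, NumericVector& imp, std::vector<int>& feat_pool) {
  int m = hi - lo;
  double sy = 0.0, syy = 0.0;
  for (int t = lo; t < hi; ++t) { sy += y[idx[t]]; syy += y[idx[t]] * y[idx[t]]; }
  double node_mean = sy / m;
  double node_sse = syy - sy * sy / m;

  int node = tr.feature.size();
  tr.feature.push_back(-1); tr.threshold.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(node_mean);
  if (m < 2 || node_sse <= 1e-12) return node;

  int p = X.ncol();
  // partial Fisher-Yates draw of mtry features
  for (int k = 0; k < mtry; ++k) {
    int j = k + (int)(R::unif_rand() * (p - k));
    if (j >= p) j = p - 1;
    std::swap(feat_pool[k], feat_pool[j]);
  }

  double best_gain = 1e-12, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double,double>> xy(m);
  for (int k = 0; k < mtry; ++k) {
    int f = feat_pool[k];
    for (int t = 0; t < m; ++t)
      xy[t] = { X(idx[lo + t], f), y[idx[lo + t]] };
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double ls = 0.0, lss = 0.0;
    for (int t = 0; t < m - 1; ++t) {
      ls += xy[t].second; lss += xy[t].second * xy[t].second;
      if (xy[t].first == xy[t + 1].first) continue;
      int nl = t + 1, nr = m - nl;
      double rs = sy - ls, rss = syy - lss;
      double gain = node_sse - (lss - ls * ls / nl) - (rss - rs * rs / nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (xy[t].first + xy[t + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_thr) std::swap(idx[mid++], idx[t]);
  if (mid == lo || mid == hi) return node;  // numerical guard

  imp[best_f] += best_gain;
  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  tr.left[node] = grow(X, y, idx, lo, mid, mtry, tr, imp, feat_pool);
  tr.right[node] = grow(X, y, idx, mid, hi, mtry, tr, imp, feat_pool);
  return node;
}

// [[Rcpp::export]]
List rf_build(NumericMatrix X, NumericVector y, int n_trees, int mtry) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector imp(p);
  List trees(n_trees);
  std::vector<int> feat_pool(p);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(R::unif_rand() * n);
      idx[i] = (j >= n) ? n - 1 : j;
    }
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    Tree tr;
    grow(X, y, idx, 0, n, mtry, tr, imp, feat_pool);
    trees[t] = List::create(
      _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
      _["threshold"] = NumericVector(tr.threshold.begin(), tr.threshold.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["value"] = NumericVector(tr.value.begin(), tr.value.end()));
  }
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  return out / T;
}
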