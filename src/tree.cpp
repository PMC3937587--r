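#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Deviance-splitting classification tree on a single continuous predictor.
// Node deviance D_m = -2 * sum_k n_mk * log(p_mk), with 0*log(0) = 0.
// Because the predictor is one-dimensional, a tree is fully described by its
// ordered interior split points ("breaks") and the per-leaf class counts: the
// leaves are the intervals (-Inf, b1], (b1, b2], ..., (b_{L-1}, Inf).
//
// sum_k n_k log(n_k / n) = sum_k n_k log n_k - n log n, so node deviances are
// computed from a precomputed c -> c*log(c) table (one entry per possible
// count), which keeps the split scan free of log() calls and allocations.

struct TreeBuild {
  const std::vector<double> &x;  // ascending
  const std::vector<int> &y;     // 0-based class codes
  int K, minsplit, minbucket;
  std::vector<double> nlogn;     // nlogn[c] = c * log(c), nlogn[0] = 0
  std::vector<double> breaks;
  std::vector<int> leaf_label;   // 0-based plurality label, ties -> lowest
  std::vector<std::vector<int> > leaf_counts;

  TreeBuild(const std::vector<double> &x_, const std::vector<int> &y_, int K_,
            int minsplit_, int minbucket_)
      : x(x_), y(y_), K(K_), minsplit(minsplit_), minbucket(minbucket_) {
    nlogn.resize(x.size() + 1);
    nlogn[0] = 0.0;
    for (size_t c = 1; c <= x.size(); ++c) nlogn[c] = c * std::log((double)c);
  }

  inline double node_dev(const int *cnt) const {
    int n = 0;
    double s = 0.0;
    for (int k = 0; k < K; ++k) { n += cnt[k]; s += nlogn[cnt[k]]; }
    if (n == 0) return 0.0;
    return -2.0 * (s - nlogn[n]);
  }

  void emit_leaf(const int *cnt) {
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (cnt[k] > cnt[best]) best = k;  // strict > keeps ties at the lower code
    leaf_label.push_back(best);
    leaf_counts.push_back(std::vector<int>(cnt, cnt + K));
  }

  void grow(int lo, int hi) {  // [lo, hi)
    int n = hi - lo;
    std::vector<int> cnt_v(K, 0), left_v(K, 0);
    int *cnt = cnt_v.data(), *left = left_v.data();
    for (int i = lo; i < hi; ++i) cnt[y[i]]++;
    int nclass = 0;
    for (int k = 0; k < K; ++k) nclass += (cnt[k] > 0);
    if (n < minsplit || nclass < 2) { emit_leaf(cnt); return; }

    double dnode = node_dev(cnt);
    double best = dnode - 1e-9;  // require a strict deviance decrease
    int best_i = -1;
    for (int i = lo; i < hi - 1; ++i) {
      left[y[i]]++;
      int nl = i - lo + 1, nr = n - nl;
      if (nl < minbucket || nr < minbucket) continue;
      if (x[i] >= x[i + 1]) continue;  // no boundary between tied values
      double sl = 0.0, sr = 0.0;
      for (int k = 0; k < K; ++k) {
        sl += nlogn[left[k]];
        sr += nlogn[cnt[k] - left[k]];
      }
      double d = -2.0 * (sl - nlogn[nl]) - 2.0 * (sr - nlogn[nr]);
      if (d < best) { best = d; best_i = i; }
    }
    if (best_i < 0) { emit_leaf(cnt); return; }
    grow(lo, best_i + 1);
    breaks.push_back(0.5 * (x[best_i] + x[best_i + 1]));
    grow(best_i + 1, hi);
  }
};

// [[Rcpp::export]]
List cpp_grow_tree(NumericVector xs, IntegerVector ys, int K, int minsplit,
                   int minbucket) {
  std::vector<double> x = as<std::vector<double> >(xs);
  std::vector<int> y = as<std::vector<int> >(ys);
  TreeBuild tb(x, y, K, minsplit, minbucket);
  if (!x.empty()) tb.grow(0, (int)x.size());
  IntegerMatrix counts(tb.leaf_counts.size(), K);
  IntegerVector labels(tb.leaf_label.size());
  for (size_t i = 0; i < tb.leaf_counts.size(); ++i) {
    labels[i] = tb.leaf_label[i] + 1;  // 1-based for R
    for (int k = 0; k < K; ++k) counts(i, k) = tb.leaf_counts[i][k];
  }
  return List::create(_["breaks"] = wrap(tb.breaks), _["labels"] = labels,
                      _["counts"] = counts);
}

static inline int leaf_of(const std::vector<double> &breaks, double v) {
  // leaf i covers (b_{i-1}, b_i]; x <= split goes left
  return (int)(std::lower_bound(breaks.begin(), breaks.end(), v) -
               breaks.begin());
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(NumericVector breaks, IntegerVector labels,
                               NumericVector newx) {
  std::vector<double> b = as<std::vector<double> >(breaks);
  IntegerVector out(newx.size());
  for (int i = 0; i < newx.size(); ++i) out[i] = labels[leaf_of(b, newx[i])];
  return out;
}

// Grow a bootstrap forest on pre-sorted training data. Each tree resamples
// the n cases with replacement (respecting the sorted order, so no per-tree
// sort) and is grown to purity (minsplit = 2, minbucket = 1). Uses R's RNG
// stream.
// [[Rcpp::export]]
List cpp_grow_forest(NumericVector xs, IntegerVector ys, int K, int ntree) {
  int n = xs.size();
  std::vector<double> x0 = as<std::vector<double> >(xs);
  std::vector<int> y0 = as<std::vector<int> >(ys);
  List trees(ntree);
  std::vector<int> draw(n);
  std::vector<double> bx;
  std::vector<int> by;
  bx.reserve(n);
  by.reserve(n);
  for (int t = 0; t < ntree; ++t) {
    std::fill(draw.begin(), draw.end(), 0);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j == n) j = n - 1;
      draw[j]++;
    }
    bx.clear();
    by.clear();
    for (int i = 0; i < n; ++i)
      for (int r = 0; r < draw[i]; ++r) { bx.push_back(x0[i]); by.push_back(y0[i]); }
    TreeBuild tb(bx, by, K, 2, 1);
    tb.grow(0, (int)bx.size());
    IntegerVector lab(tb.leaf_label.size());
    for (size_t i = 0; i < tb.leaf_label.size(); ++i) lab[i] = tb.leaf_label[i];
    trees[t] = List::create(_["breaks"] = wrap(tb.breaks), _["labels"] = lab);
  }
  return trees;
}

// Majority vote of a forest over new predictor values; returns the K-column
// vote count matrix (forest leaf labels are 0-based internally).
// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(List trees, NumericVector newx, int K) {
  int n = newx.size();
  IntegerMatrix votes(n, K);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    std::vector<double> b = as<std::vector<double> >((SEXP)tr["breaks"]);
    IntegerVector lab = tr["labels"];
    for (int i = 0; i < n; ++i) votes(i, lab[leaf_of(b, newx[i])])++;
  }
  return votes;
}
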