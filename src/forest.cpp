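#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// CART regression trees and a bagged forest with impurity (SSE-decrease)
// variable importance. Splits minimize within-node sum of squares; candidate
// features are an mtry-subset drawn per node. Randomness comes from R's RNG
// so results are reproducible under set.seed().

struct TreeBuilder {
  const NumericMatrix &X;
  const NumericVector &y;
  int mtry, min_node, max_depth;
  std::vector<double> feature, threshold, value;
  std::vector<int> left, right;
  std::vector<double> &imp; // per-feature impurity decrease accumulator

  TreeBuilder(const NumericMatrix &X_, const NumericVector &y_,
              int mtry_, int min_node_, int max_depth_, std::vector<double> &imp_)
    : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_), imp(imp_) {}

  int build(std::vector<int> &idx, int lo, int hi, int depth) {
    const int n = hi - lo;
    double sum = 0.0, sumsq = 0.0;
    for (int i = lo; i < hi; ++i) { sum += y[idx[i]]; sumsq += y[idx[i]] * y[idx[i]]; }
    const double mean = sum / n;
    const double ss = sumsq - sum * sum / n;
    const int node = (int)feature.size();
    feature.push_back(-1); threshold.push_back(0);
    left.push_back(-1); right.push_back(-1); value.push_back(mean);
    if (n < min_node || depth >= max_depth || ss <= 1e-12) return node;

    const int p = X.ncol();
    // mtry features without replacement (partial Fisher-Yates via R RNG)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    const int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<int> node_idx(idx.begin() + lo, idx.begin() + hi);
    for (int j = 0; j < m; ++j) {
      const int f = feats[j];
      std::sort(node_idx.begin(), node_idx.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += y[node_idx[i]];
        if (X(node_idx[i + 1], f) <= X(node_idx[i], f)) continue;
        const int nl = i + 1, nr2 = n - nl;
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr2 - sum * sum / n;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (X(node_idx[i], f) + X(node_idx[i + 1], f));
        }
      }
    }
    if (best_feat < 0) return node;

    imp[best_feat] += best_gain;
    // partition idx[lo:hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return node; // numeric degeneracy guard
    feature[node] = best_feat; threshold[node] = best_thr;
    const int l = build(idx, lo, mid, depth + 1);
    left[node] = l;
    const int r = build(idx, mid, hi, depth + 1);
    right[node] = r;
    return node;
  }

  NumericMatrix as_matrix() const {
    const int k = (int)feature.size();
    NumericMatrix out(k, 5);
    for (int i = 0; i < k; ++i) {
      out(i, 0) = feature[i]; out(i, 1) = threshold[i];
      out(i, 2) = left[i]; out(i, 3) = right[i]; out(i, 4) = value[i];
    }
    return out;
  }
};

static double tree_predict_row(const NumericMatrix &tree, const NumericMatrix &X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int mtry, int min_node, int max_depth) {
  std::vector<double> imp(X.ncol(), 0.0);
  TreeBuilder tb(X, y, mtry, min_node, max_depth, imp);
  std::vector<int> idx(rows.begin(), rows.end()); // 0-based
  tb.build(idx, 0, (int)idx.size(), 0);
  return List::create(_["tree"] = tb.as_matrix(),
                      _["importance"] = NumericVector(imp.begin(), imp.end()));
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int ntree,
                    int mtry, int min_node, int max_depth) {
  const int n = X.nrow();
  List trees(ntree);
  std::vector<double> imp(X.ncol(), 0.0);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    std::vector<double> imp_b(X.ncol(), 0.0);
    TreeBuilder tb(X, y, mtry, min_node, max_depth, imp_b);
    tb.build(idx, 0, n, 0);
    trees[b] = tb.as_matrix();
    for (int j = 0; j < X.ncol(); ++j) imp[j] += imp_b[j];
  }
  for (int j = 0; j < X.ncol(); ++j) imp[j] /= ntree;
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(imp.begin(), imp.end()));
}

// [[Rcpp::export]]
NumericVector cpp_trees_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tr = trees[b];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(NumericMatrix tree, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tree_predict_row(tree, X, i);
  return out;
}
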