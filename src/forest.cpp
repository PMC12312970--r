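#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Random forest for binary voxel classification (CART trees, Gini impurity,
// bootstrap resampling, per-split feature subsampling). Uses R's RNG, so
// training is reproducible under set.seed(). Trees are returned as flat
// numeric matrices (feature, threshold, left, right, prob) so a fitted model
// is an ordinary R list and serializes with base R.

struct TreeNode {
  int feature;   // -1 for leaf
  double thresh;
  int left, right;
  double prob;   // class-1 fraction of training samples in node
};

static int grow_node(std::vector<TreeNode> &nodes, const NumericMatrix &X,
                     const IntegerVector &y, std::vector<int> &samp,
                     int lo, int hi, int depth, int mtry, int min_node,
                     int max_depth) {
  const int m = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[samp[i]];
  double p1 = (double)pos / m;

  int self = (int)nodes.size();
  nodes.push_back(TreeNode{-1, 0.0, -1, -1, p1});
  if (pos == 0 || pos == m || m < 2 * min_node || depth >= max_depth)
    return self;

  const int p = X.ncol();
  // feature subsample without replacement (partial Fisher-Yates, R RNG)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int ntry = std::min(mtry, p);
  for (int j = 0; j < ntry; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double best_gain = 0.0, best_thresh = 0.0;
  int best_feat = -1;
  double parent_imp = p1 * (1.0 - p1);
  std::vector<std::pair<double, int> > vals(m);

  for (int j = 0; j < ntry; ++j) {
    int f = feats[j];
    for (int i = 0; i < m; ++i) {
      int s = samp[lo + i];
      vals[i] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int i = 0; i < m - 1; ++i) {
      lpos += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = m - nl;
      if (nl < min_node || nr < min_node) continue;
      double pl = (double)lpos / nl, pr = (double)(pos - lpos) / nr;
      double imp = ((double)nl / m) * pl * (1 - pl) +
                   ((double)nr / m) * pr * (1 - pr);
      double gain = parent_imp - imp;
      if (gain > best_gain + 1e-15) {
        best_gain = gain;
        best_feat = f;
        best_thresh = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_feat < 0) return self;

  // partition samp[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(samp[i], best_feat) <= best_thresh) std::swap(samp[i], samp[mid++]);
  if (mid == lo || mid == hi) return self;

  nodes[self].feature = best_feat;
  nodes[self].thresh = best_thresh;
  int l = grow_node(nodes, X, y, samp, lo, mid, depth + 1, mtry, min_node,
                    max_depth);
  int r = grow_node(nodes, X, y, samp, mid, hi, depth + 1, mtry, min_node,
                    max_depth);
  nodes[self].left = l;
  nodes[self].right = r;
  return self;
}

// [[Rcpp::export(name = ".cpp_rf_train")]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, int max_depth) {
  const int n = X.nrow();
  List forest(n_trees);
  std::vector<int> samp(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      samp[i] = k;
    }
    std::vector<TreeNode> nodes;
    nodes.reserve(64);
    grow_node(nodes, X, y, samp, 0, n, 0, mtry, min_node, max_depth);
    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t i = 0; i < nodes.size(); ++i) {
      tm(i, 0) = nodes[i].feature;
      tm(i, 1) = nodes[i].thresh;
      tm(i, 2) = nodes[i].left;
      tm(i, 3) = nodes[i].right;
      tm(i, 4) = nodes[i].prob;
    }
    forest[t] = tm;
  }
  return forest;
}

// [[Rcpp::export(name = ".cpp_rf_predict")]]
NumericVector cpp_rf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = forest.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    NumericMatrix tm = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tm(node, 0) >= 0) {
        int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      out[i] += tm(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= n_trees;
  return out;
}
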