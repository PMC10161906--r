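// Classification trees and bagged/random forests for binary labels.
//
// Deliberately minimal CART: Gini impurity, axis-aligned splits on
// continuous features, depth and leaf-size controls, optional per-split
// feature subsampling (mtry) and bootstrap resampling for forests. Leaves
// store the positive-class proportion so predictions are probabilities.
// Determinism: all randomness comes from a std::mt19937 seeded by the
// caller; ties in the split search are broken by the first (feature, value)
// pair encountered in index order.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids, -1 for leaf
  double prob;      // P(y = 1) among training rows in this node
  int n;            // training rows in this node
};

struct Tree {
  std::vector<Node> nodes;
};

// Best split of rows (index set) on one feature: midpoint thresholds between
// consecutive distinct sorted values; returns impurity decrease achieved.
static bool best_split_on_feature(const NumericMatrix& X, const IntegerVector& y,
                                  const std::vector<int>& rows, int j,
                                  int min_leaf, double& best_gain,
                                  double& best_thr) {
  const int n = rows.size();
  std::vector<std::pair<double, int>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {X(rows[i], j), y[rows[i]]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;

  int total_pos = 0;
  for (auto& p : v) total_pos += p.second;
  const double parent_imp =
      1.0 - (double)total_pos / n * total_pos / n -
      (double)(n - total_pos) / n * (n - total_pos) / n;

  bool found = false;
  int left_pos = 0;
  for (int i = 0; i < n - 1; ++i) {
    left_pos += v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    const int nl = i + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    const int rp = total_pos - left_pos;
    const double gl = 1.0 - (double)left_pos / nl * left_pos / nl -
                      (double)(nl - left_pos) / nl * (nl - left_pos) / nl;
    const double gr = 1.0 - (double)rp / nr * rp / nr -
                      (double)(nr - rp) / nr * (nr - rp) / nr;
    const double gain = parent_imp - ((double)nl / n) * gl - ((double)nr / n) * gr;
    if (gain > best_gain + 1e-12) {
      best_gain = gain;
      best_thr = (v[i].first + v[i + 1].first) / 2.0;
      found = true;
    }
  }
  return found;
}

static int grow(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
                std::vector<int>& rows, int depth, int max_depth, int min_leaf,
                int mtry, std::mt19937& rng) {
  const int n = rows.size();
  int pos = 0;
  for (int r : rows) pos += y[r];

  Node node;
  node.feature = -1; node.threshold = 0.0;
  node.left = node.right = -1;
  node.prob = (double)pos / n;
  node.n = n;

  const int id = tree.nodes.size();
  tree.nodes.push_back(node);

  if (depth >= max_depth || n < 2 * min_leaf || pos == 0 || pos == n)
    return id;

  const int d = X.ncol();
  std::vector<int> feats(d);
  for (int j = 0; j < d; ++j) feats[j] = j;
  if (mtry < d) {
    // partial Fisher-Yates: first mtry entries are the sampled features,
    // kept in ascending order afterwards for deterministic tie-breaking
    for (int i = 0; i < mtry; ++i) {
      std::uniform_int_distribution<int> u(i, d - 1);
      std::swap(feats[i], feats[u(rng)]);
    }
    feats.resize(mtry);
    std::sort(feats.begin(), feats.end());
  }

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  for (int j : feats) {
    double g = best_gain, t = 0.0;
    if (best_split_on_feature(X, y, rows, j, min_leaf, g, t)) {
      best_gain = g; best_thr = t; best_feat = j;
    }
  }
  if (best_feat < 0) return id;

  std::vector<int> left_rows, right_rows;
  for (int r : rows) {
    if (X(r, best_feat) <= best_thr) left_rows.push_back(r);
    else right_rows.push_back(r);
  }
  if (left_rows.empty() || right_rows.empty()) return id;

  tree.nodes[id].feature = best_feat;
  tree.nodes[id].threshold = best_thr;
  const int l = grow(tree, X, y, left_rows, depth + 1, max_depth, min_leaf, mtry, rng);
  tree.nodes[id].left = l;
  const int r = grow(tree, X, y, right_rows, depth + 1, max_depth, min_leaf, mtry, rng);
  tree.nodes[id].right = r;
  return id;
}

static NumericMatrix tree_to_matrix(const Tree& tree) {
  const int m = tree.nodes.size();
  NumericMatrix out(m, 6);
  for (int i = 0; i < m; ++i) {
    const Node& nd = tree.nodes[i];
    out(i, 0) = nd.feature; out(i, 1) = nd.threshold;
    out(i, 2) = nd.left;    out(i, 3) = nd.right;
    out(i, 4) = nd.prob;    out(i, 5) = nd.n;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "prob", "n");
  return out;
}

static double predict_row(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    node = (X(row, (int)tree(node, 0)) <= tree(node, 1))
             ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

// [[Rcpp::export(name = ".cart_fit")]]
NumericMatrix cart_fit(NumericMatrix X, IntegerVector y, int max_depth,
                       int min_leaf) {
  Tree tree;
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::mt19937 rng(1u); // unused when mtry == ncol
  grow(tree, X, y, rows, 0, max_depth, min_leaf, X.ncol(), rng);
  return tree_to_matrix(tree);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(NumericMatrix tree, NumericMatrix X) {
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = predict_row(tree, X, i);
  return out;
}

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, IntegerVector y, int n_tree, int max_depth,
                int min_leaf, int mtry, int seed) {
  std::mt19937 rng((unsigned)seed);
  const int n = X.nrow();
  List trees(n_tree);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int b = 0; b < n_tree; ++b) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = boot(rng);
    std::sort(rows.begin(), rows.end());
    Tree tree;
    grow(tree, X, y, rows, 0, max_depth, min_leaf, mtry, rng);
    trees[b] = tree_to_matrix(tree);
  }
  return trees;
}

// Mean leaf probability over the first n_tree trees (n_tree <= length(trees)),
// so nested grids over tree counts can reuse one fitted forest.
// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X, int n_tree) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int b = 0; b < n_tree; ++b) {
    NumericMatrix tree = trees[b];
    for (int i = 0; i < n; ++i) out[i] += predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= n_tree;
  return out;
}
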