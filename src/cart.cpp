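// Weighted classification trees (CART, gini impurity) for the in-package
// AdaBoost stumps and random forest. Numeric features only, binary labels
// {0,1}, per-sample weights. Trees are flat integer/double vectors so they
// serialize trivially and predict fast.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> prob;     // weighted P(y=1) in node
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double impurity = R_PosInf;
};

// Best weighted-gini split over a feature subset for the samples in idx.
static SplitResult best_split(const NumericMatrix& X,
                              const IntegerVector& y,
                              const NumericVector& w,
                              const std::vector<int>& idx,
                              const std::vector<int>& feats,
                              int min_node) {
  SplitResult best;
  const int m = idx.size();
  std::vector<int> ord(m);
  std::vector<double> xv(m), wv(m), wy(m);

  for (int f : feats) {
    for (int i = 0; i < m; ++i) xv[i] = X(idx[i], f);
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    double Wtot = 0.0, W1tot = 0.0;
    for (int i = 0; i < m; ++i) {
      wv[i] = w[idx[ord[i]]];
      wy[i] = wv[i] * y[idx[ord[i]]];
      Wtot += wv[i];
      W1tot += wy[i];
    }
    double Wl = 0.0, W1l = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      Wl += wv[i];
      W1l += wy[i];
      double x_here = xv[ord[i]], x_next = xv[ord[i + 1]];
      if (x_here == x_next) continue;
      if (i + 1 < min_node || m - (i + 1) < min_node) continue;
      double Wr = Wtot - Wl, W1r = W1tot - W1l;
      if (Wl <= 0.0 || Wr <= 0.0) continue;
      double p1l = W1l / Wl, p1r = W1r / Wr;
      double imp = Wl * 2.0 * p1l * (1.0 - p1l) +
                   Wr * 2.0 * p1r * (1.0 - p1r);
      if (imp < best.impurity) {
        best.impurity = imp;
        best.feature = f;
        best.threshold = 0.5 * (x_here + x_next);
      }
    }
  }
  return best;
}

static int grow(TreeBuf& T, const NumericMatrix& X, const IntegerVector& y,
                const NumericVector& w, std::vector<int>& idx, int depth,
                int mtry, int max_depth, int min_node, std::mt19937& rng) {
  double Wtot = 0.0, W1 = 0.0;
  for (int i : idx) { Wtot += w[i]; W1 += w[i] * y[i]; }
  double p1 = (Wtot > 0.0) ? W1 / Wtot : 0.5;

  int node = T.feature.size();
  T.feature.push_back(-1);
  T.threshold.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.prob.push_back(p1);

  if (depth >= max_depth || (int)idx.size() < 2 * min_node ||
      p1 <= 0.0 || p1 >= 1.0)
    return node;

  const int p = X.ncol();
  std::vector<int> feats(p);
  std::iota(feats.begin(), feats.end(), 0);
  if (mtry < p) {
    for (int i = 0; i < mtry; ++i) {
      std::uniform_int_distribution<int> pick(i, p - 1);
      std::swap(feats[i], feats[pick(rng)]);
    }
    feats.resize(mtry);
  }

  SplitResult s = best_split(X, y, w, idx, feats, min_node);
  if (s.feature < 0) return node;

  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, s.feature) <= s.threshold) li.push_back(i);
    else ri.push_back(i);
  }
  if (li.empty() || ri.empty()) return node;

  T.feature[node] = s.feature;
  T.threshold[node] = s.threshold;
  int l = grow(T, X, y, w, li, depth + 1, mtry, max_depth, min_node, rng);
  int r = grow(T, X, y, w, ri, depth + 1, mtry, max_depth, min_node, rng);
  T.left[node] = l;
  T.right[node] = r;
  return node;
}

static List pack(const TreeBuf& T) {
  return List::create(_["feature"] = wrap(T.feature),
                      _["threshold"] = wrap(T.threshold),
                      _["left"] = wrap(T.left),
                      _["right"] = wrap(T.right),
                      _["prob"] = wrap(T.prob));
}

// [[Rcpp::export]]
List cart_build(NumericMatrix X, IntegerVector y, NumericVector w,
                int mtry, int max_depth, int min_node, int seed) {
  std::mt19937 rng(seed);
  TreeBuf T;
  std::vector<int> idx(X.nrow());
  std::iota(idx.begin(), idx.end(), 0);
  grow(T, X, y, w, idx, 0, mtry, max_depth, min_node, rng);
  return pack(T);
}

static double predict_one(const IntegerVector& feature,
                          const NumericVector& threshold,
                          const IntegerVector& left,
                          const IntegerVector& right,
                          const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return node;
}

// [[Rcpp::export]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], prob = tree["prob"];
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = prob[(int)predict_one(feature, threshold, left, right, X, i)];
  return out;
}

// Bagged forest: bootstrap resampling and per-node feature subsampling,
// all driven by one mt19937 seed for reproducibility.
// [[Rcpp::export]]
List cart_forest_build(NumericMatrix X, IntegerVector y, int n_trees,
                       int mtry, int max_depth, int min_node, int seed) {
  std::mt19937 rng(seed);
  const int n = X.nrow();
  NumericVector w(n);
  List forest(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int i = 0; i < n; ++i) w[pick(rng)] += 1.0;
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) if (w[i] > 0.0) idx.push_back(i);
    TreeBuf T;
    grow(T, X, y, w, idx, 0, mtry, max_depth, min_node, rng);
    forest[t] = pack(T);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cart_forest_predict(List forest, NumericMatrix X) {
  NumericVector out(X.nrow());
  for (int t = 0; t < forest.size(); ++t) {
    NumericVector p = cart_predict(forest[t], X);
    for (int i = 0; i < X.nrow(); ++i) out[i] += p[i];
  }
  return out / (double)forest.size();
}
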