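// Random-forest classifier for 2-s EEG segments: bootstrapped CART trees
// grown to full splits (Gini, midpoint thresholds, mtry random candidate
// features per node).  A private mt19937 stream keeps training
// deterministic for a given seed across platforms.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;    // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> pred;    // leaf class-1 fraction
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry;
  std::mt19937& rng;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), rng(rng_), feat_pool(X_.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int new_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0.0);
    return (int)tree.feature.size() - 1;
  }

  int build(std::vector<int>& idx) {
    int node = new_node();
    int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    tree.pred[node] = (double)pos / n;
    if (pos == 0 || pos == n || n < 2) return node;

    // sample mtry candidate features without replacement
    for (int k = 0; k < mtry; ++k) {
      std::uniform_int_distribution<int> d(k, (int)feat_pool.size() - 1);
      std::swap(feat_pool[k], feat_pool[d(rng)]);
    }

    double best_score = -1.0;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int k = 0; k < mtry; ++k) {
      int f = feat_pool[k];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int left_n = 0, left_pos = 0;
      for (int i = 0; i < n - 1; ++i) {
        left_n++;
        left_pos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int right_n = n - left_n;
        int right_pos = pos - left_pos;
        // Gini decrease up to constants: maximize negative weighted impurity
        double gl = (double)left_pos * left_pos / left_n +
                    (double)(left_n - left_pos) * (left_n - left_pos) / left_n;
        double gr = (double)right_pos * right_pos / right_n +
                    (double)(right_n - right_pos) * (right_n - right_pos) / right_n;
        double score = gl + gr;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
        }
      }
    }
    if (best_f < 0) return node;  // all candidates constant -> leaf

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(li);
    int r = build(ri);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  List forest(n_trees);
  IntegerMatrix inbag(n, n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = boot(rng);
      inbag(idx[i], t)++;
    }
    Builder b(X, y, mtry, rng);
    b.build(idx);
    forest[t] = List::create(
        _["feature"] = IntegerVector(b.tree.feature.begin(), b.tree.feature.end()),
        _["threshold"] = NumericVector(b.tree.threshold.begin(), b.tree.threshold.end()),
        _["left"] = IntegerVector(b.tree.left.begin(), b.tree.left.end()),
        _["right"] = IntegerVector(b.tree.right.begin(), b.tree.right.end()),
        _["pred"] = NumericVector(b.tree.pred.begin(), b.tree.pred.end()));
  }
  return List::create(_["trees"] = forest, _["inbag"] = inbag);
}

// Out-of-bag votes for the training rows themselves: each row is scored
// only by the trees whose bootstrap sample excluded it.  Rows in-bag for
// every tree (vanishingly rare) fall back to the full ensemble.
// [[Rcpp::export]]
NumericVector rf_predict_oob_cpp(List forest, NumericMatrix X,
                                 IntegerMatrix inbag) {
  int n = X.nrow();
  int n_trees = forest.size();
  NumericVector votes(n);
  IntegerVector used(n);
  for (int t = 0; t < n_trees; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      if (inbag(i, t) > 0) continue;
      int node = 0;
      while (feature[node] >= 0) {
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      }
      votes[i] += pred[node] >= 0.5 ? 1.0 : 0.0;
      used[i]++;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = used[i] > 0 ? votes[i] / used[i] : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow();
  int n_trees = forest.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      }
      // full-split leaves are (near) pure: vote by majority of the leaf
      out[i] += pred[node] >= 0.5 ? 1.0 : 0.0;
    }
  }
  return out / (double)n_trees;
}
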