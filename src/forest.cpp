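#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Compact CART regression forest: bootstrap rows, mtry feature subsample per
// node, best-split by SSE reduction, grow until node size <= nodesize.
// Uses R's RNG so results are reproducible under set.seed().

namespace {

struct Tree {
  // flat node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double score = -1.0;  // SSE reduction proxy (sum of child S^2/n minus parent)
};

// find best split among `mtry` sampled features for rows idx[lo..hi)
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       std::vector<int>& idx, int lo, int hi, int mtry,
                       std::vector<int>& feat_pool,
                       std::vector<std::pair<double, double>>& buf) {
  const int m = hi - lo;
  const int p = X.ncol();
  double sum = 0.0;
  for (int k = lo; k < hi; ++k) sum += y[idx[k]];
  const double parent = sum * sum / m;

  SplitResult best;
  // partial Fisher-Yates over feature pool
  for (int t = 0; t < mtry; ++t) {
    int j = t + (int)(unif_rand() * (p - t));
    if (j >= p) j = p - 1;
    std::swap(feat_pool[t], feat_pool[j]);
    const int f = feat_pool[t];

    buf.resize(m);
    for (int k = 0; k < m; ++k)
      buf[k] = std::make_pair(X(idx[lo + k], f), y[idx[lo + k]]);
    std::sort(buf.begin(), buf.end(),
              [](const std::pair<double, double>& a,
                 const std::pair<double, double>& b) { return a.first < b.first; });
    if (buf.front().first == buf.back().first) continue;  // constant in node

    double ls = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      ls += buf[k].second;
      if (buf[k].first == buf[k + 1].first) continue;  // can't split between ties
      const int nl = k + 1, nr = m - nl;
      const double rs = sum - ls;
      const double score = ls * ls / nl + rs * rs / nr - parent;
      if (score > best.score) {
        best.score = score;
        best.feature = f;
        best.threshold = 0.5 * (buf[k].first + buf[k + 1].first);
      }
    }
  }
  return best;
}

void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int mtry, int nodesize, Tree& tree) {
  const int p = X.ncol();
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  std::vector<std::pair<double, double>> buf;

  // stack of (lo, hi, node_id) spans over idx
  struct Span { int lo, hi, node; };
  std::vector<Span> stack;

  auto new_node = [&tree]() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    return (int)tree.feature.size() - 1;
  };

  int root = new_node();
  stack.push_back({0, (int)idx.size(), root});

  while (!stack.empty()) {
    Span s = stack.back();
    stack.pop_back();
    const int m = s.hi - s.lo;
    double sum = 0.0;
    for (int k = s.lo; k < s.hi; ++k) sum += y[idx[k]];
    tree.value[s.node] = sum / m;
    if (m <= nodesize) continue;

    SplitResult sp = best_split(X, y, idx, s.lo, s.hi, mtry, feat_pool, buf);
    if (sp.feature < 0 || sp.score <= 1e-12) continue;

    // partition idx[lo,hi) in place
    int i = s.lo, j = s.hi - 1;
    while (i <= j) {
      if (X(idx[i], sp.feature) <= sp.threshold) {
        ++i;
      } else {
        std::swap(idx[i], idx[j]);
        --j;
      }
    }
    const int mid = i;
    if (mid == s.lo || mid == s.hi) continue;  // numeric edge case

    tree.feature[s.node] = sp.feature;
    tree.threshold[s.node] = sp.threshold;
    int l = new_node(), r = new_node();
    tree.left[s.node] = l;
    tree.right[s.node] = r;
    stack.push_back({s.lo, mid, l});
    stack.push_back({mid, s.hi, r});
  }
}

double predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    node = (X(row, tree.feature[node]) <= tree.threshold[node]) ? tree.left[node]
                                                                : tree.right[node];
  }
  return tree.value[node];
}

Tree tree_from_list(const List& tl) {
  Tree t;
  IntegerVector f = tl["feature"], l = tl["left"], r = tl["right"];
  NumericVector th = tl["threshold"], v = tl["value"];
  t.feature.assign(f.begin(), f.end());
  t.left.assign(l.begin(), l.end());
  t.right.assign(r.begin(), r.end());
  t.threshold.assign(th.begin(), th.end());
  t.value.assign(v.begin(), v.end());
  return t;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int ntree, int mtry,
                     int nodesize) {
  const int n = X.nrow();
  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);
  std::vector<char> inbag(n);
  std::vector<int> idx;
  idx.reserve(n);

  for (int b = 0; b < ntree; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int k = 0; k < n; ++k) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx.push_back(r);
      inbag[r] = 1;
    }
    Tree tree;
    grow_tree(X, y, idx, mtry, nodesize, tree);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_one(tree, X, i);
        oob_cnt[i] += 1;
      }
    }
    trees[b] = List::create(
        _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
        _["threshold"] = NumericVector(tree.threshold.begin(), tree.threshold.end()),
        _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
        _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
        _["value"] = NumericVector(tree.value.begin(), tree.value.end()));
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }

  double oob_mse = NA_REAL;
  int used = 0;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      const double e = y[i] - oob_sum[i] / oob_cnt[i];
      acc += e * e;
      ++used;
    }
  }
  if (used > 0) oob_mse = acc / used;

  return List::create(_["trees"] = trees, _["oob_mse"] = oob_mse);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = trees.size();
  std::vector<Tree> parsed;
  parsed.reserve(ntree);
  for (int b = 0; b < ntree; ++b) parsed.push_back(tree_from_list(trees[b]));

  NumericVector out(n, 0.0);
  for (int b = 0; b < ntree; ++b) {
    const Tree& t = parsed[b];
    for (int i = 0; i < n; ++i) out[i] += predict_one(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// Permutation importance: %IncMSE per feature on supplied (held-out) data.
// For each feature and repeat, permute that column (R RNG), recompute MSE.
// [[Rcpp::export]]
NumericVector cpp_permutation_importance(List trees, NumericMatrix X,
                                         NumericVector y, int n_repeats) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int ntree = trees.size();
  std::vector<Tree> parsed;
  parsed.reserve(ntree);
  for (int b = 0; b < ntree; ++b) parsed.push_back(tree_from_list(trees[b]));

  auto mse_of = [&](const NumericMatrix& M) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      double pr = 0.0;
      for (int b = 0; b < ntree; ++b) pr += predict_one(parsed[b], M, i);
      pr /= ntree;
      const double e = y[i] - pr;
      acc += e * e;
    }
    return acc / n;
  };

  const double base = mse_of(X);
  NumericVector imp(p, 0.0);
  NumericMatrix W = clone(X);
  std::vector<double> orig(n);
  std::vector<int> perm(n);

  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) orig[i] = X(i, f);
    double acc = 0.0;
    for (int rep = 0; rep < n_repeats; ++rep) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      for (int i = 0; i < n; ++i) W(i, f) = orig[perm[i]];
      acc += mse_of(W);
    }
    for (int i = 0; i < n; ++i) W(i, f) = orig[i];
    imp[f] = 100.0 * (acc / n_repeats - base) / base;
    Rcpp::checkUserInterrupt();
  }
  return imp;
}
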