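#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tolerance for "strictly better" comparisons of gains / gain ratios.
// Scores are O(1) bits, so an absolute epsilon is adequate.
static const double SCORE_EPS = 1e-12;

static inline double log2d(double x) { return std::log(x) / M_LN2; }

static double entropy_counts(const std::vector<int>& cnt, int n) {
  double e = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    if (cnt[c] > 0) {
      double p = static_cast<double>(cnt[c]) / n;
      e -= p * log2d(p);
    }
  }
  return e;
}

struct BestSplit {
  bool found;
  int gene;          // 0-based column
  double thr, gain, split_info, ratio;
};

// Exhaustive gene x midpoint-threshold search maximizing gain ratio among
// candidates with information gain > 0 and both branches >= min_leaf.
// Ties resolve to higher gain, then lower gene index, then lower threshold
// (the scan order makes the last two automatic under strict improvement).
static BestSplit find_best_split(const NumericMatrix& X, const IntegerVector& y,
                                 const std::vector<int>& idx, int K, int min_leaf) {
  BestSplit bs;
  bs.found = false; bs.gene = -1; bs.thr = 0.0;
  bs.gain = -1.0; bs.split_info = 0.0; bs.ratio = -1.0;

  const int n = static_cast<int>(idx.size());
  const int p = X.ncol();
  if (n < 2 * min_leaf || p == 0) return bs;

  std::vector<int> parent(K, 0);
  for (int i = 0; i < n; ++i) parent[y[idx[i]]]++;
  double hP = entropy_counts(parent, n);

  std::vector<std::pair<double, int> > vals(n);
  std::vector<int> leftc(K), rightc(K);

  for (int g = 0; g < p; ++g) {
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[i], g), y[idx[i]]);
    std::sort(vals.begin(), vals.end());

    std::fill(leftc.begin(), leftc.end(), 0);
    rightc = parent;

    for (int i = 1; i < n; ++i) {
      int lab = vals[i - 1].second;
      leftc[lab]++; rightc[lab]--;
      if (!(vals[i].first > vals[i - 1].first)) continue;  // not a boundary
      int nL = i, nR = n - i;
      if (nL < min_leaf || nR < min_leaf) continue;
      double pL = static_cast<double>(nL) / n, pR = static_cast<double>(nR) / n;
      double gain = hP - pL * entropy_counts(leftc, nL) - pR * entropy_counts(rightc, nR);
      if (gain <= SCORE_EPS) continue;
      double si = -pL * log2d(pL) - pR * log2d(pR);
      double ratio = gain / si;
      bool better = (ratio > bs.ratio + SCORE_EPS) ||
                    (std::fabs(ratio - bs.ratio) <= SCORE_EPS && gain > bs.gain + SCORE_EPS);
      if (!bs.found || better) {
        bs.found = true;
        bs.gene = g;
        bs.thr = (vals[i - 1].first + vals[i].first) / 2.0;
        bs.gain = gain; bs.split_info = si; bs.ratio = ratio;
      }
    }
  }
  return bs;
}

struct FlatTree {
  std::vector<int> gene;        // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right; // -1 for leaf
  std::vector<int> pred;        // 0-based majority class (tie -> lowest index)
  std::vector<std::vector<int> > counts;
};

static int majority_class(const std::vector<int>& cnt) {
  int b = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[b]) b = static_cast<int>(c);
  return b;
}

static int grow_node(const NumericMatrix& X, const IntegerVector& y,
                     const std::vector<int>& idx, int K, int min_leaf,
                     int max_depth, int depth, FlatTree& T) {
  const int n = static_cast<int>(idx.size());
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[y[idx[i]]]++;

  int id = static_cast<int>(T.gene.size());
  T.gene.push_back(-1);
  T.thr.push_back(NA_REAL);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back(majority_class(cnt));
  T.counts.push_back(cnt);

  int n_classes_here = 0;
  for (int c = 0; c < K; ++c) if (cnt[c] > 0) n_classes_here++;
  if (n_classes_here <= 1) return id;
  if (max_depth >= 0 && depth >= max_depth) return id;

  BestSplit bs = find_best_split(X, y, idx, K, min_leaf);
  if (!bs.found) return id;

  std::vector<int> li, ri;
  li.reserve(n); ri.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], bs.gene) <= bs.thr) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  T.gene[id] = bs.gene;
  T.thr[id] = bs.thr;
  T.left[id] = grow_node(X, y, li, K, min_leaf, max_depth, depth + 1, T);
  T.right[id] = grow_node(X, y, ri, K, min_leaf, max_depth, depth + 1, T);
  return id;
}

static FlatTree grow_full(const NumericMatrix& X, const IntegerVector& y,
                          int K, int min_leaf, int max_depth) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  FlatTree T;
  grow_node(X, y, idx, K, min_leaf, max_depth, 0, T);
  return T;
}

// [[Rcpp::export(name = ".cpp_best_split")]]
SEXP cpp_best_split(NumericMatrix X, IntegerVector y, int K, int min_leaf) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  BestSplit bs = find_best_split(X, y, idx, K, min_leaf);
  if (!bs.found) return R_NilValue;
  return List::create(_["gene_index"] = bs.gene + 1,
                      _["threshold"] = bs.thr,
                      _["gain"] = bs.gain,
                      _["split_info"] = bs.split_info,
                      _["gain_ratio"] = bs.ratio);
}

// [[Rcpp::export(name = ".cpp_grow")]]
List cpp_grow(NumericMatrix X, IntegerVector y, int K, int min_leaf, int max_depth) {
  FlatTree T = grow_full(X, y, K, min_leaf, max_depth);
  const int m = static_cast<int>(T.gene.size());
  IntegerVector gene(m), left(m), right(m), pred(m);
  NumericVector thr(m);
  IntegerMatrix counts(m, K);
  for (int i = 0; i < m; ++i) {
    gene[i] = (T.gene[i] < 0) ? NA_INTEGER : T.gene[i] + 1;
    thr[i] = T.thr[i];
    left[i] = (T.left[i] < 0) ? NA_INTEGER : T.left[i] + 1;
    right[i] = (T.right[i] < 0) ? NA_INTEGER : T.right[i] + 1;
    pred[i] = T.pred[i] + 1;
    for (int c = 0; c < K; ++c) counts(i, c) = T.counts[i][c];
  }
  return List::create(_["gene"] = gene, _["threshold"] = thr,
                      _["left"] = left, _["right"] = right,
                      _["pred"] = pred, _["counts"] = counts);
}

// Grow on (Xtr, ytr), score on (Xte, yte). One call per CV fold keeps the
// PSO fitness loop out of interpreted code.
// [[Rcpp::export(name = ".cpp_holdout_accuracy")]]
double cpp_holdout_accuracy(NumericMatrix Xtr, IntegerVector ytr,
                            NumericMatrix Xte, IntegerVector yte,
                            int K, int min_leaf, int max_depth) {
  FlatTree T = grow_full(Xtr, ytr, K, min_leaf, max_depth);
  int correct = 0;
  const int nte = Xte.nrow();
  for (int i = 0; i < nte; ++i) {
    int node = 0;
    while (T.gene[node] >= 0)
      node = (Xte(i, T.gene[node]) <= T.thr[node]) ? T.left[node] : T.right[node];
    if (T.pred[node] == yte[i]) correct++;
  }
  return nte > 0 ? static_cast<double>(correct) / nte : NA_REAL;
}
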