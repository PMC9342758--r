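#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// Random forest of CART-style (Gini) classification trees grown on
// without-replacement subsamples. Binary response y in {0,1}
// (1 = "used"). Propensity = fraction of trees voting class 1, where a
// tree's vote is the majority class of the leaf (ties vote 0.5).

namespace {

struct Forest {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;  // leaf fraction of class 1
  std::vector<int> tree_start; // size ntrees+1, node offsets
};

inline double leaf_vote(double frac) {
  if (frac > 0.5) return 1.0;
  if (frac < 0.5) return 0.0;
  return 0.5;
}

// traverse one tree; if ov_feat >= 0 use ov_val for that feature
double tree_value(const Forest& f, int t, const double* xrow, int n,
                  int ov_feat, double ov_val, const NumericMatrix& X, int row) {
  int node = f.tree_start[t];
  while (f.feature[node] >= 0) {
    int ft = f.feature[node];
    double v = (ft == ov_feat) ? ov_val : X(row, ft);
    node = (v <= f.thr[node]) ? f.left[node] : f.right[node];
  }
  (void)xrow; (void)n;
  return f.value[node];
}

void grow_tree(Forest& fo, const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int lo0, int hi0, int mtry, int min_node,
               std::mt19937_64& rng) {
  int p = X.ncol();
  int minsplit = std::max(2, min_node);
  // stack of (node array position, lo, hi)
  struct Item { int node, lo, hi; };
  std::vector<Item> stack;
  std::vector<int> feats(p);
  for (int i = 0; i < p; i++) feats[i] = i;
  std::vector<std::pair<double,int> > buf;

  // root
  fo.feature.push_back(-1); fo.thr.push_back(0.0);
  fo.left.push_back(-1); fo.right.push_back(-1); fo.value.push_back(0.0);
  int root = (int)fo.feature.size() - 1;
  stack.push_back(Item{root, lo0, hi0});

  while (!stack.empty()) {
    Item it = stack.back();
    stack.pop_back();
    int lo = it.lo, hi = it.hi, n = hi - lo;
    int pos = 0;
    for (int i = lo; i < hi; i++) pos += y[idx[i]];
    double frac = (double)pos / n;
    fo.value[it.node] = frac;
    if (pos == 0 || pos == n || n < minsplit) continue; // leaf

    double parent = 2.0 * (double)pos * (n - pos) / n;
    double best_score = parent - 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;

    // sample mtry features without replacement (partial Fisher-Yates)
    int m = std::min(mtry, p);
    for (int i = 0; i < m; i++) {
      std::uniform_int_distribution<int> U(i, p - 1);
      std::swap(feats[i], feats[U(rng)]);
    }
    for (int fi = 0; fi < m; fi++) {
      int f = feats[fi];
      buf.clear();
      for (int i = lo; i < hi; i++)
        buf.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
      std::sort(buf.begin(), buf.end(),
                [](const std::pair<double,int>& a, const std::pair<double,int>& b) {
                  return a.first < b.first;
                });
      int nL = 0, posL = 0;
      for (int i = 0; i < n - 1; i++) {
        nL++;
        posL += buf[i].second;
        if (buf[i].first == buf[i + 1].first) continue;
        int nR = n - nL, posR = pos - posL;
        double score = 2.0 * (double)posL * (nL - posL) / nL +
                       2.0 * (double)posR * (nR - posR) / nR;
        if (score < best_score) {
          best_score = score;
          best_feat = f;
          best_thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
        }
      }
    }
    if (best_feat < 0) continue; // no usable split -> leaf

    // partition idx[lo,hi) by x <= thr
    int mid = lo;
    for (int i = lo; i < hi; i++) {
      if (X(idx[i], best_feat) <= best_thr) {
        std::swap(idx[i], idx[mid]);
        mid++;
      }
    }
    // children
    fo.feature.push_back(-1); fo.thr.push_back(0.0);
    fo.left.push_back(-1); fo.right.push_back(-1); fo.value.push_back(0.0);
    int lchild = (int)fo.feature.size() - 1;
    fo.feature.push_back(-1); fo.thr.push_back(0.0);
    fo.left.push_back(-1); fo.right.push_back(-1); fo.value.push_back(0.0);
    int rchild = (int)fo.feature.size() - 1;
    fo.feature[it.node] = best_feat;
    fo.thr[it.node] = best_thr;
    fo.left[it.node] = lchild;
    fo.right[it.node] = rchild;
    stack.push_back(Item{lchild, lo, mid});
    stack.push_back(Item{rchild, mid, hi});
  }
}

Forest forest_from_list(const List& fl) {
  Forest fo;
  IntegerVector feature = fl["feature"], left = fl["left"], right = fl["right"],
                tree_start = fl["tree_start"];
  NumericVector thr = fl["thr"], value = fl["value"];
  fo.feature.assign(feature.begin(), feature.end());
  fo.thr.assign(thr.begin(), thr.end());
  fo.left.assign(left.begin(), left.end());
  fo.right.assign(right.begin(), right.end());
  fo.value.assign(value.begin(), value.end());
  fo.tree_start.assign(tree_start.begin(), tree_start.end());
  return fo;
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int ntrees, int mtry,
                double frac, int min_node, int seed) {
  int n = X.nrow();
  int ns = (int)std::lround(frac * n);
  if (ns < 1) ns = 1;
  if (ns > n) ns = n;
  std::mt19937_64 rng((uint64_t)seed);
  Forest fo;
  fo.tree_start.push_back(0);
  RawMatrix inbag(n, ntrees);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<int> perm(n), idx(ns);
  for (int i = 0; i < n; i++) perm[i] = i;

  for (int t = 0; t < ntrees; t++) {
    // subsample without replacement
    for (int i = 0; i < ns; i++) {
      std::uniform_int_distribution<int> U(i, n - 1);
      std::swap(perm[i], perm[U(rng)]);
    }
    for (int i = 0; i < ns; i++) idx[i] = perm[i];
    for (int i = 0; i < n; i++) inbag(i, t) = 0;
    for (int i = 0; i < ns; i++) inbag(idx[i], t) = 1;
    grow_tree(fo, X, y, idx, 0, ns, mtry, min_node, rng);
    fo.tree_start.push_back((int)fo.feature.size());
    // OOB votes for this tree
    for (int i = 0; i < n; i++) {
      if (inbag(i, t)) continue;
      double v = tree_value(fo, t, NULL, 0, -1, 0.0, X, i);
      oob_sum[i] += leaf_vote(v);
      oob_cnt[i]++;
    }
  }
  NumericVector oob_vote(n);
  IntegerVector oob_n(n);
  for (int i = 0; i < n; i++) {
    oob_n[i] = oob_cnt[i];
    oob_vote[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  }
  return List::create(
      _["feature"] = IntegerVector(fo.feature.begin(), fo.feature.end()),
      _["thr"] = NumericVector(fo.thr.begin(), fo.thr.end()),
      _["left"] = IntegerVector(fo.left.begin(), fo.left.end()),
      _["right"] = IntegerVector(fo.right.begin(), fo.right.end()),
      _["value"] = NumericVector(fo.value.begin(), fo.value.end()),
      _["tree_start"] = IntegerVector(fo.tree_start.begin(), fo.tree_start.end()),
      _["inbag"] = inbag, _["oob_vote"] = oob_vote, _["oob_n"] = oob_n);
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List fl, NumericMatrix X) {
  Forest fo = forest_from_list(fl);
  int ntrees = (int)fo.tree_start.size() - 1;
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int t = 0; t < ntrees; t++)
      s += leaf_vote(tree_value(fo, t, NULL, 0, -1, 0.0, X, i));
    out[i] = s / ntrees;
  }
  return out;
}

// Partial dependence: for each grid value g of feature `feat` (0-based),
// the mean vote fraction over all rows with that feature forced to g.
// [[Rcpp::export]]
NumericVector cpp_rf_pdp(List fl, NumericMatrix X, int feat,
                         NumericVector grid) {
  Forest fo = forest_from_list(fl);
  int ntrees = (int)fo.tree_start.size() - 1;
  int n = X.nrow(), m = grid.size();
  NumericVector out(m);
  for (int k = 0; k < m; k++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) {
      double rowsum = 0.0;
      for (int t = 0; t < ntrees; t++)
        rowsum += leaf_vote(tree_value(fo, t, NULL, 0, feat, grid[k], X, i));
      s += rowsum / ntrees;
    }
    out[k] = s / n;
  }
  return out;
}

// Per-tree permutation importance: returns p x ntrees matrix of
// (OOB accuracy - OOB accuracy with feature permuted), averaged over reps.
// [[Rcpp::export]]
NumericMatrix cpp_rf_importance(List fl, NumericMatrix X, IntegerVector y,
                                RawMatrix inbag, int nreps, int seed) {
  Forest fo = forest_from_list(fl);
  int ntrees = (int)fo.tree_start.size() - 1;
  int n = X.nrow(), p = X.ncol();
  std::mt19937_64 rng((uint64_t)seed);
  NumericMatrix out(p, ntrees);
  std::vector<int> oob;
  std::vector<double> col;
  for (int t = 0; t < ntrees; t++) {
    oob.clear();
    for (int i = 0; i < n; i++)
      if (!inbag(i, t)) oob.push_back(i);
    int m = (int)oob.size();
    if (m == 0) continue;
    int correct = 0;
    for (int k = 0; k < m; k++) {
      double v = leaf_vote(tree_value(fo, t, NULL, 0, -1, 0.0, X, oob[k]));
      if ((v > 0.5 ? 1 : 0) == y[oob[k]]) correct++;
    }
    double base = (double)correct / m;
    for (int f = 0; f < p; f++) {
      double dec = 0.0;
      for (int rep = 0; rep < nreps; rep++) {
        col.resize(m);
        for (int k = 0; k < m; k++) col[k] = X(oob[k], f);
        for (int k = m - 1; k > 0; k--) {
          std::uniform_int_distribution<int> U(0, k);
          std::swap(col[k], col[U(rng)]);
        }
        int corr = 0;
        for (int k = 0; k < m; k++) {
          double v = leaf_vote(tree_value(fo, t, NULL, 0, f, col[k], X, oob[k]));
          if ((v > 0.5 ? 1 : 0) == y[oob[k]]) corr++;
        }
        dec += base - (double)corr / m;
      }
      out(f, t) = dec / nreps;
    }
  }
  return out;
}
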