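// Regression random forest with out-of-bag permutation importance.
// CART trees, bootstrap per tree, mtry features per split, exhaustive
// best-split search minimising within-node SSE. Uses R's RNG throughout so
// results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;              // -1 marks a leaf
  std::vector<double> thr, val;
  std::vector<int> left, right;
  int new_node() {
    feat.push_back(-1); thr.push_back(0.0); val.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    return (int)feat.size() - 1;
  }
};

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Work { int lo, hi, node; };

void build_tree(const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int mtry, int nodesize, Tree& t) {
  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::vector<std::pair<double, double> > buf;
  std::vector<Work> stack;
  Work root = {0, (int)idx.size(), t.new_node()};
  stack.push_back(root);
  while (!stack.empty()) {
    Work w = stack.back(); stack.pop_back();
    const int n = w.hi - w.lo;
    double sy = 0.0, syy = 0.0;
    for (int i = w.lo; i < w.hi; ++i) { double v = y[idx[i]]; sy += v; syy += v * v; }
    const double mean = sy / n;
    if (n <= nodesize || syy - sy * sy / n <= 1e-12) {
      t.val[w.node] = mean; continue;
    }
    int bestf = -1; double bestthr = 0.0, bestgain = -1.0;
    for (int k = 0; k < mtry && k < p; ++k) {
      int r = k + rand_int(p - k);
      std::swap(feats[k], feats[r]);
      const int f = feats[k];
      buf.clear();
      for (int i = w.lo; i < w.hi; ++i)
        buf.push_back(std::make_pair(X(idx[i], f), y[idx[i]]));
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;
      double ls = 0.0; int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        ls += buf[i].second; ++nl;
        if (buf[i].first == buf[i + 1].first) continue;
        const double rs = sy - ls; const int nr = n - nl;
        const double gain = ls * ls / nl + rs * rs / nr;
        if (gain > bestgain) {
          bestgain = gain; bestf = f;
          bestthr = 0.5 * (buf[i].first + buf[i + 1].first);
        }
      }
    }
    if (bestf < 0) { t.val[w.node] = mean; continue; }
    int mid = w.lo;
    for (int i = w.lo; i < w.hi; ++i)
      if (X(idx[i], bestf) <= bestthr) std::swap(idx[i], idx[mid++]);
    if (mid == w.lo || mid == w.hi) { t.val[w.node] = mean; continue; }
    const int L = t.new_node(), R = t.new_node();
    t.feat[w.node] = bestf; t.thr[w.node] = bestthr;
    t.left[w.node] = L; t.right[w.node] = R;
    Work wl = {w.lo, mid, L}, wr = {mid, w.hi, R};
    stack.push_back(wl); stack.push_back(wr);
  }
}

// prediction for row i, optionally overriding feature permf with value pv
double predict_one(const Tree& t, const NumericMatrix& X, int i,
                   int permf, double pv) {
  int node = 0;
  while (t.feat[node] >= 0) {
    const int f = t.feat[node];
    const double v = (f == permf) ? pv : X(i, f);
    node = (v <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.val[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_forest")]]
List rf_forest(NumericMatrix X, NumericVector y, int ntree, int mtry,
               int nodesize, bool importance) {
  RNGScope scope;
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  NumericMatrix imp_tree(importance ? ntree : 0, importance ? p : 0);
  std::vector<char> inbag(n);
  std::vector<int> idx, oob, perm;
  idx.reserve(n); oob.reserve(n);
  for (int b = 0; b < ntree; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) { int k = rand_int(n); idx.push_back(k); inbag[k] = 1; }
    Tree t;
    build_tree(X, y, idx, mtry, nodesize, t);
    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    const int m = (int)oob.size();
    double mse0 = 0.0;
    for (int k = 0; k < m; ++k) {
      const double pr = predict_one(t, X, oob[k], -1, 0.0);
      oob_sum[oob[k]] += pr; oob_cnt[oob[k]] += 1;
      const double e = pr - y[oob[k]];
      mse0 += e * e;
    }
    mse0 /= m;
    if (importance) {
      perm.resize(m);
      for (int k = 0; k < m; ++k) perm[k] = k;
      for (int f = 0; f < p; ++f) {
        for (int k = m - 1; k > 0; --k) std::swap(perm[k], perm[rand_int(k + 1)]);
        double mse = 0.0;
        for (int k = 0; k < m; ++k) {
          const double xv = X(oob[perm[k]], f);
          const double e = predict_one(t, X, oob[k], f, xv) - y[oob[k]];
          mse += e * e;
        }
        imp_tree(b, f) = mse / m - mse0;
      }
    }
  }
  double mse = 0.0; int cnt = 0;
  for (int i = 0; i < n; ++i) if (oob_cnt[i] > 0) {
    const double e = oob_sum[i] / oob_cnt[i] - y[i];
    mse += e * e; ++cnt;
  }
  NumericVector imp_mean(p, NA_REAL), imp_sd(p, NA_REAL);
  if (importance) {
    for (int f = 0; f < p; ++f) {
      double s = 0.0, ss = 0.0;
      for (int b = 0; b < ntree; ++b) { s += imp_tree(b, f); ss += imp_tree(b, f) * imp_tree(b, f); }
      imp_mean[f] = s / ntree;
      imp_sd[f] = ntree > 1 ? sqrt(std::max(0.0, (ss - s * s / ntree) / (ntree - 1))) : NA_REAL;
    }
  }
  return List::create(
    _["oob_mse"] = cnt > 0 ? mse / cnt : NA_REAL,
    _["imp_mean"] = imp_mean,
    _["imp_sd_trees"] = imp_sd,
    _["n_oob_mean"] = ntree > 0 ? (double)n * std::pow(1.0 - 1.0 / n, (double)n) : NA_REAL);
}
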