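// Tree ensemble with weighted split-candidate sampling.
//
// The ensemble is a plain CART-style classification forest except for one
// step: the mtry candidate features at every node are drawn without
// replacement with probability proportional to a per-feature weight vector
// (uniform weights recover the conventional random forest).  Sampling uses
// exponential keys (Efraimidis & Spirakis): feature j gets key
// Exp(1)/w_j and the mtry smallest keys are kept, which reproduces exactly
// the successive draw-proportional-to-weight / remove / renormalize scheme.
//
// All randomness flows through a splitmix64 stream seeded per tree from the
// master seed, so results are bit-reproducible across platforms and ntree
// can grow without reshuffling earlier trees.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on [0, 1)
  double unif() { return (double)(next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

uint64_t tree_seed(double master, int t) {
  return (uint64_t)master * 0x9E3779B97F4A7C15ULL + (uint64_t)(t + 1) * 0xBF58476D1CE4E5B9ULL;
}

// mtry distinct indices, draw order, probability of each successive draw
// proportional to remaining weights; zero-weight features are never drawn.
void weighted_draw(const std::vector<double>& w, int mtry, Rng& rng,
                   std::vector<int>& out) {
  const int p = (int)w.size();
  std::vector<std::pair<double, int> > keys;
  keys.reserve(p);
  for (int j = 0; j < p; ++j) {
    if (w[j] > 0.0) {
      double u = rng.unif();
      if (u <= 0.0) u = 1e-300;
      keys.push_back(std::make_pair(-std::log(u) / w[j], j));
    }
  }
  if ((int)keys.size() < mtry)
    stop("fewer positive-weight features (%d) than mtry (%d)",
         (int)keys.size(), mtry);
  std::partial_sort(keys.begin(), keys.begin() + mtry, keys.end());
  out.resize(mtry);
  for (int k = 0; k < mtry; ++k) out[k] = keys[k].second;
}

struct Split {
  int feature;
  double threshold;
  double improvement;
  Split() : feature(-1), threshold(0.0), improvement(0.0) {}
};

// impurity mass: n * Gini or n * entropy, from class counts
inline double impurity_mass(const std::vector<int>& cnt, int n, int rule) {
  if (n == 0) return 0.0;
  double s;
  if (rule == 0) {  // gini
    s = (double)n;
    for (size_t k = 0; k < cnt.size(); ++k)
      s -= (double)cnt[k] * (double)cnt[k] / (double)n;
  } else {          // entropy
    s = 0.0;
    for (size_t k = 0; k < cnt.size(); ++k)
      if (cnt[k] > 0)
        s -= (double)cnt[k] * std::log((double)cnt[k] / (double)n);
  }
  return s;
}

// Best (feature, threshold) over sorted candidate features; thresholds at
// midpoints between consecutive distinct sorted values.  Ties in improvement
// are broken toward the lower feature index, then the lower threshold, by
// scanning candidates in ascending index order and accepting only strict
// improvements.
Split find_best_split(const NumericMatrix& X, const IntegerVector& y,
                      const std::vector<int>& rows,
                      std::vector<int>& cand, int K, int rule) {
  const int n = (int)rows.size();
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[y[rows[i]]]++;
  const double parent = impurity_mass(cnt, n, rule);

  std::sort(cand.begin(), cand.end());
  Split best;
  best.improvement = 1e-12;  // a split must strictly decrease impurity

  std::vector<std::pair<double, int> > vals(n);
  std::vector<int> lcnt(K), rcnt(K);
  for (size_t c = 0; c < cand.size(); ++c) {
    const int g = cand[c];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[i], g), y[rows[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int k = 0; k < K; ++k) rcnt[k] = cnt[k];
    int nl = 0;
    for (int i = 0; i + 1 < n; ++i) {
      const int lab = vals[i].second;
      lcnt[lab]++; rcnt[lab]--; nl++;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nr = n - nl;
      const double child =
          impurity_mass(lcnt, nl, rule) + impurity_mass(rcnt, nr, rule);
      const double imp = parent - child;
      if (imp > best.improvement + 1e-12) {
        best.improvement = imp;
        best.feature = g;
        best.threshold = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
      }
    }
  }
  return best;
}

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // 0-based node ids, -1 for leaf
  std::vector<int> pred;         // majority class at node (ties: lowest class index)
};

int grow_node(const NumericMatrix& X, const IntegerVector& y,
              const std::vector<double>& w, std::vector<int>& rows,
              int K, int mtry, int min_node_size, int rule,
              Rng& rng, Tree& tree, std::vector<int>& sel_counts) {
  const int id = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);

  std::vector<int> cnt(K, 0);
  const int n = (int)rows.size();
  for (int i = 0; i < n; ++i) cnt[y[rows[i]]]++;
  int maj = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[maj]) maj = k;
  tree.pred.push_back(maj);

  bool pure = (cnt[maj] == n);
  if (pure || n <= min_node_size) return id;

  std::vector<int> cand;
  weighted_draw(w, mtry, rng, cand);
  Split s = find_best_split(X, y, rows, cand, K, rule);
  if (s.feature < 0) return id;

  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(rows[i], s.feature) <= s.threshold) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  // a midpoint threshold always separates at least one row each side
  tree.feature[id] = s.feature;
  tree.threshold[id] = s.threshold;
  sel_counts[s.feature]++;
  rows.clear(); rows.shrink_to_fit();
  const int lid = grow_node(X, y, w, lrows, K, mtry, min_node_size, rule,
                            rng, tree, sel_counts);
  const int rid = grow_node(X, y, w, rrows, K, mtry, min_node_size, rule,
                            rng, tree, sel_counts);
  tree.left[id] = lid;
  tree.right[id] = rid;
  return id;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int K, NumericVector w,
                     int ntree, int mtry, int min_node_size, int split_rule,
                     double seed) {
  const int n = X.nrow();
  const int p = X.ncol();
  std::vector<double> wv(w.begin(), w.end());

  List trees(ntree);
  std::vector<int> sel_counts(p, 0);
  IntegerVector bag_unique(ntree);

  for (int t = 0; t < ntree; ++t) {
    Rng rng(tree_seed(seed, t));
    std::vector<int> rows(n);
    std::vector<char> seen(n, 0);
    for (int i = 0; i < n; ++i) {
      rows[i] = rng.below(n);
      seen[rows[i]] = 1;
    }
    int uniq = 0;
    for (int i = 0; i < n; ++i) uniq += seen[i];
    bag_unique[t] = uniq;

    Tree tree;
    grow_node(X, y, wv, rows, K, mtry, min_node_size, split_rule,
              rng, tree, sel_counts);
    trees[t] = List::create(
        Named("feature") = IntegerVector(tree.feature.begin(), tree.feature.end()),
        Named("threshold") = NumericVector(tree.threshold.begin(), tree.threshold.end()),
        Named("left") = IntegerVector(tree.left.begin(), tree.left.end()),
        Named("right") = IntegerVector(tree.right.begin(), tree.right.end()),
        Named("pred") = IntegerVector(tree.pred.begin(), tree.pred.end()));
  }

  return List::create(
      Named("trees") = trees,
      Named("selection_counts") = IntegerVector(sel_counts.begin(), sel_counts.end()),
      Named("bag_unique") = bag_unique);
}

// [[Rcpp::export]]
IntegerMatrix cpp_predict_forest(List trees, NumericMatrix X, int K) {
  const int n = X.nrow();
  const int ntree = trees.size();
  IntegerMatrix votes(n, K);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      votes(i, pred[node])++;
    }
  }
  return votes;
}

// [[Rcpp::export]]
IntegerVector cpp_draw_candidates(NumericVector w, int mtry, double seed) {
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x94D049BB133111EBULL);
  std::vector<double> wv(w.begin(), w.end());
  std::vector<int> out;
  weighted_draw(wv, mtry, rng, out);
  IntegerVector res(mtry);
  for (int k = 0; k < mtry; ++k) res[k] = out[k] + 1;  // 1-based, draw order
  return res;
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, IntegerVector y, int K,
                    IntegerVector candidates, int split_rule) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  for (size_t c = 0; c < cand.size(); ++c) cand[c] -= 1;  // to 0-based
  Split s = find_best_split(X, y, rows, cand, K, split_rule);
  return List::create(Named("feature") = s.feature + 1,  // 0 means none
                      Named("threshold") = s.threshold,
                      Named("improvement") = s.improvement);
}
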