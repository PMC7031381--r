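// Seeded random forest for binary classification on small feature matrices.
// CART trees with the Gini criterion, bootstrap sampling, majority-vote
// leaves; vote ratios as scores and out-of-bag permutation importance
// (mean decrease in accuracy, z-scaled over trees).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> vote;      // leaf class vote (0/1)
};

static double gini_impurity(int n0, int n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

// Best threshold split for one feature over the node's samples.
// Returns impurity decrease (weighted), or -1 if no valid split.
static double best_split_feature(const NumericMatrix& X,
                                 const IntegerVector& y,
                                 const std::vector<int>& idx,
                                 int f, double& thr_out) {
  size_t n = idx.size();
  std::vector<std::pair<double, int>> v(n);
  for (size_t i = 0; i < n; ++i)
    v[i] = {X(idx[i], f), y[idx[i]]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return -1.0;
  int tot1 = 0;
  for (auto& p : v) tot1 += p.second;
  int tot0 = (int)n - tot1;
  double parent = gini_impurity(tot0, tot1);
  int l0 = 0, l1 = 0;
  double best = -1.0;
  for (size_t i = 0; i + 1 < n; ++i) {
    if (v[i].second) ++l1; else ++l0;
    if (v[i].first == v[i + 1].first) continue;
    int r0 = tot0 - l0, r1 = tot1 - l1;
    double nl = l0 + l1, nr = r0 + r1;
    double dec = parent - (nl / n) * gini_impurity(l0, l1)
                        - (nr / n) * gini_impurity(r0, r1);
    if (dec > best) {
      best = dec;
      thr_out = (v[i].first + v[i + 1].first) / 2.0;
    }
  }
  return best;
}

static int grow_node(Tree& tree, const NumericMatrix& X,
                     const IntegerVector& y, std::vector<int>& idx,
                     int mtry, int nodesize, std::mt19937& rng) {
  int node = (int)tree.feat.size();
  tree.feat.push_back(-1); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.vote.push_back(0);

  int n1 = 0;
  for (int i : idx) n1 += y[i];
  int n0 = (int)idx.size() - n1;

  bool leaf = (n0 == 0 || n1 == 0 || (int)idx.size() < 2 * nodesize);
  int p = X.ncol();
  int bestf = -1;
  double bestdec = 0.0, bestthr = 0.0;
  if (!leaf) {
    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
      double thr;
      double dec = best_split_feature(X, y, idx, feats[j], thr);
      if (dec > bestdec) { bestdec = dec; bestf = feats[j]; bestthr = thr; }
    }
    if (bestf < 0) leaf = true;
  }
  if (leaf) {
    int v = (n1 * 2 > (int)idx.size()) ? 1
          : (n1 * 2 < (int)idx.size()) ? 0
          : (int)(rng() & 1);  // deterministic-under-seed tie break
    tree.vote[node] = v;
    return node;
  }
  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, bestf) <= bestthr) li.push_back(i); else ri.push_back(i);
  }
  tree.feat[node] = bestf;
  tree.thr[node] = bestthr;
  tree.left[node] = grow_node(tree, X, y, li, mtry, nodesize, rng);
  tree.right[node] = grow_node(tree, X, y, ri, mtry, nodesize, rng);
  return node;
}

static int tree_predict_row(const Tree& t, const NumericMatrix& X, int row,
                            const int* perm, int permfeat) {
  int node = 0;
  while (t.feat[node] >= 0) {
    int f = t.feat[node];
    int r = (perm != nullptr && f == permfeat) ? perm[row] : row;
    node = (X(r, f) <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.vote[node];
}

static List tree_to_list(const Tree& t) {
  return List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["vote"] = wrap(t.vote));
}

static Tree tree_from_list(const List& l) {
  Tree t;
  t.feat = as<std::vector<int>>(l["feat"]);
  t.thr = as<std::vector<double>>(l["thr"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.vote = as<std::vector<int>>(l["vote"]);
  return t;
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int nodesize, int seed) {
  int n = X.nrow();
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    std::mt19937 rng((unsigned)seed + 0x9e3779b9u * (unsigned)(t + 1));
    std::uniform_int_distribution<int> U(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = U(rng);
      inbag(idx[i], t) += 1;
    }
    Tree tree;
    grow_node(tree, X, y, idx, mtry, nodesize, rng);
    trees[t] = tree_to_list(tree);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["ntree"] = ntree);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int ntree = trees.size();
  int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i)
      out[i] += tree_predict_row(tr, X, i, nullptr, -1);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export]]
List rf_importance_cpp(List forest, NumericMatrix X, IntegerVector y,
                       int seed) {
  List trees = forest["trees"];
  IntegerMatrix inbag = forest["inbag"];
  int ntree = trees.size();
  int n = X.nrow(), p = X.ncol();
  NumericMatrix decr(ntree, p);  // per-tree accuracy decrease
  std::vector<char> used(ntree, 0);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    if (oob.empty()) continue;
    used[t] = 1;
    double acc = 0.0;
    for (int i : oob)
      acc += (tree_predict_row(tr, X, i, nullptr, -1) == y[i]);
    acc /= oob.size();
    std::mt19937 rng((unsigned)seed + 0x85ebca6bu * (unsigned)(t + 1));
    // one shared OOB permutation per tree-feature, applied to feature f
    std::vector<int> perm_of(n, 0);
    for (int f = 0; f < p; ++f) {
      std::vector<int> shuffled = oob;
      std::shuffle(shuffled.begin(), shuffled.end(), rng);
      for (int i = 0; i < n; ++i) perm_of[i] = i;
      for (size_t k = 0; k < oob.size(); ++k) perm_of[oob[k]] = shuffled[k];
      double accp = 0.0;
      for (int i : oob)
        accp += (tree_predict_row(tr, X, i, perm_of.data(), f) == y[i]);
      accp /= oob.size();
      decr(t, f) = acc - accp;
    }
  }
  NumericVector raw(p), sdv(p), scaled(p);
  int nused = 0;
  for (int t = 0; t < ntree; ++t) nused += used[t];
  for (int f = 0; f < p; ++f) {
    double s = 0.0;
    for (int t = 0; t < ntree; ++t) if (used[t]) s += decr(t, f);
    double mean = (nused > 0) ? s / nused : 0.0;
    double ss = 0.0;
    for (int t = 0; t < ntree; ++t)
      if (used[t]) ss += (decr(t, f) - mean) * (decr(t, f) - mean);
    double sd = (nused > 1) ? std::sqrt(ss / (nused - 1)) : 0.0;
    raw[f] = mean;
    sdv[f] = sd;
    scaled[f] = (sd > 0) ? mean / (sd / std::sqrt((double)nused)) : 0.0;
  }
  return List::create(_["raw"] = raw, _["sd"] = sdv, _["scaled"] = scaled,
                      _["n_trees_used"] = nused);
}
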