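// Bagged CART regression forest used as probability forest for binary
// targets. Hand-rolled because the deployment image carries no tree
// learner; interface is deliberately minimal: fit on (X, y), predict a
// test matrix in the same call. All randomness flows through R's RNG so
// set.seed() on the R side makes results reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // flat arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;
};

struct NodeJob {
  int node;
  int begin;  // range into idx
  int end;
  int depth;
};

// draw k of p features without replacement (partial Fisher-Yates)
inline void draw_features(std::vector<int>& pool, int k, std::vector<int>& out) {
  const int p = static_cast<int>(pool.size());
  for (int j = 0; j < k; ++j) {
    int pick = j + static_cast<int>(::unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(pool[j], pool[pick]);
    out[j] = pool[j];
  }
}

void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int mtry, int max_depth,
               int min_leaf, Tree& tree) {
  const int p = X.ncol();
  std::vector<int> pool(p);
  for (int j = 0; j < p; ++j) pool[j] = j;
  std::vector<int> feats(mtry);
  std::vector<std::pair<double, int> > buf;

  // root
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(0.0);

  std::vector<NodeJob> stack;
  NodeJob root = {0, 0, static_cast<int>(idx.size()), 0};
  stack.push_back(root);

  while (!stack.empty()) {
    NodeJob job = stack.back();
    stack.pop_back();
    const int n_node = job.end - job.begin;

    double sum = 0.0;
    for (int i = job.begin; i < job.end; ++i) sum += y[idx[i]];
    const double mean = sum / n_node;
    tree.value[job.node] = mean;

    if (job.depth >= max_depth || n_node < 2 * min_leaf) continue;

    // best split over an mtry-subset of features
    double best_gain = 0.0;
    int best_feat = -1;
    double best_thr = 0.0;
    draw_features(pool, mtry, feats);

    for (int fj = 0; fj < mtry; ++fj) {
      const int f = feats[fj];
      buf.clear();
      for (int i = job.begin; i < job.end; ++i)
        buf.push_back(std::make_pair(X(idx[i], f), idx[i]));
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;

      double sum_left = 0.0;
      const double base = sum * sum / n_node;
      for (int i = 0; i < n_node - 1; ++i) {
        sum_left += y[buf[i].second];
        if (buf[i].first == buf[i + 1].first) continue;
        const int n_left = i + 1;
        const int n_right = n_node - n_left;
        if (n_left < min_leaf || n_right < min_leaf) continue;
        const double sum_right = sum - sum_left;
        const double gain = sum_left * sum_left / n_left +
                            sum_right * sum_right / n_right - base;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (buf[i].first + buf[i + 1].first);
        }
      }
    }

    if (best_feat < 0) continue;

    // partition idx range in place
    int mid = job.begin;
    for (int i = job.begin; i < job.end; ++i)
      if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == job.begin || mid == job.end) continue;  // numeric ties guard

    const int li = static_cast<int>(tree.feature.size());
    for (int c = 0; c < 2; ++c) {
      tree.feature.push_back(-1);
      tree.threshold.push_back(0.0);
      tree.left.push_back(-1);
      tree.right.push_back(-1);
      tree.value.push_back(0.0);
    }
    tree.feature[job.node] = best_feat;
    tree.threshold[job.node] = best_thr;
    tree.left[job.node] = li;
    tree.right[job.node] = li + 1;

    NodeJob l = {li, job.begin, mid, job.depth + 1};
    NodeJob r = {li + 1, mid, job.end, job.depth + 1};
    stack.push_back(l);
    stack.push_back(r);
  }
}

inline double predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0)
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
               ? tree.left[node] : tree.right[node];
  return tree.value[node];
}

}  // namespace

//' @noRd
// [[Rcpp::export(rng = true)]]
NumericVector forest_fit_predict(NumericMatrix X, NumericVector y,
                                 NumericMatrix Xtest, int n_trees,
                                 int mtry, int max_depth, int min_leaf) {
  const int n = X.nrow();
  const int nt = Xtest.nrow();
  if (y.size() != n) stop("length(y) must match nrow(X)");
  if (mtry < 1 || mtry > X.ncol()) stop("invalid mtry");
  if (max_depth < 1) stop("max_depth must be >= 1");

  NumericVector out(nt, 0.0);
  std::vector<int> idx(n);

  for (int t = 0; t < n_trees; ++t) {
    // bootstrap sample
    for (int i = 0; i < n; ++i) {
      int pick = static_cast<int>(::unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    Tree tree;
    grow_tree(X, y, idx, mtry, max_depth, min_leaf, tree);
    for (int i = 0; i < nt; ++i) out[i] += predict_one(tree, Xtest, i);
  }
  for (int i = 0; i < nt; ++i) out[i] /= n_trees;
  return out;
}
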