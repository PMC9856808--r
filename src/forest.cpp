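// Bagged classification-tree ensemble with Gini-impurity splits and
// mean-decrease-in-impurity feature importances (normalized to sum 1 per
// tree, averaged over trees).  Continuous features are quantile-binned per
// fit (histogram splits), which bounds per-node work at O(n + bins) per
// candidate feature.  All randomness comes from an internal counter-based
// generator seeded from R, so a fit is bit-reproducible for a given seed
// regardless of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64: tiny, well-mixed, deterministic across platforms
struct SplitRng {
  uint64_t state;
  explicit SplitRng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature;       // split feature, -1 at leaves
  std::vector<double> threshold;  // go left iff x <= threshold
  std::vector<int> left;
  std::vector<int> right;
  std::vector<int> leaf_class;
};

struct NodeJob {
  int start, end;  // range in the bootstrap index workspace
  int n0, n1;      // class counts in the range
  int node_id;
};

// count-scaled Gini: n * (1 - sum p_k^2); additive over children
inline double gini_n(int n0, int n1) {
  const double n = static_cast<double>(n0 + n1);
  if (n <= 0.0) return 0.0;
  return n - (static_cast<double>(n0) * n0 + static_cast<double>(n1) * n1) / n;
}

}  // namespace

// X: samples x features (column-major, so one feature is contiguous)
// y: 0/1 class labels, length nrow(X)
// train_idx / eval_idx: 0-based row indices into X
// Returns impurity importances over all features, eval-set predictions,
// and the per-tree vote matrix is collapsed to majority (ties -> class 0).
// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, IntegerVector train_idx,
                IntegerVector eval_idx, int n_trees, int mtry, double seed,
                int max_bins = 64) {
  const int p = X.ncol();
  const int n_train = train_idx.size();
  const int n_eval = eval_idx.size();
  if (n_train < 2) stop("need at least 2 training samples");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (max_bins < 2 || max_bins > 255) stop("max_bins must be in [2, 255]");

  SplitRng rng(static_cast<uint64_t>(seed));

  // ---- quantile binning of the training rows, one code per (feature, row)
  std::vector<uint8_t> bin_code(static_cast<size_t>(p) * n_train);
  std::vector<std::vector<double>> edges(p);  // edges[f][b]: bin b iff x <= edges[f][b]
  {
    std::vector<double> vals(n_train);
    for (int f = 0; f < p; ++f) {
      const double* col = &X(0, f);
      for (int i = 0; i < n_train; ++i) vals[i] = col[train_idx[i]];
      std::vector<double> sorted(vals);
      std::sort(sorted.begin(), sorted.end());
      sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
      const int m = static_cast<int>(sorted.size());
      std::vector<double>& e = edges[f];
      if (m <= max_bins) {
        e = sorted;
      } else {
        e.reserve(max_bins);
        for (int j = 1; j <= max_bins; ++j) {
          int k = static_cast<int>((static_cast<long long>(j) * m) / max_bins) - 1;
          if (k < 0) k = 0;
          e.push_back(sorted[k]);
        }
        e.erase(std::unique(e.begin(), e.end()), e.end());
      }
      for (int i = 0; i < n_train; ++i) {
        int b = static_cast<int>(
            std::lower_bound(e.begin(), e.end(), vals[i]) - e.begin());
        bin_code[static_cast<size_t>(f) * n_train + i] = static_cast<uint8_t>(b);
      }
    }
  }

  std::vector<int> y_train(n_train);
  for (int i = 0; i < n_train; ++i) y_train[i] = y[train_idx[i]];

  NumericVector importance(p);
  std::vector<double> tree_imp(p);
  std::vector<int> votes1(n_eval, 0);

  std::vector<int> boot(n_train);
  std::vector<int> feat_pool(p);
  std::vector<int> cnt0(256, 0), cnt1(256, 0);  // kept clean between nodes
  std::vector<int> node_y(n_train);
  const int SMALL_NODE = 24;  // below this, sort beats the histogram
  std::vector<uint16_t> small_buf(SMALL_NODE);

  for (int t = 0; t < n_trees; ++t) {
    // bootstrap of the training rows
    int root0 = 0, root1 = 0;
    for (int i = 0; i < n_train; ++i) {
      boot[i] = rng.below(n_train);
      if (y_train[boot[i]] == 1) ++root1; else ++root0;
    }
    std::fill(tree_imp.begin(), tree_imp.end(), 0.0);
    for (int f = 0; f < p; ++f) feat_pool[f] = f;

    Tree tree;
    std::vector<NodeJob> stack;
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.leaf_class.push_back(root1 > root0 ? 1 : 0);
    stack.push_back({0, n_train, root0, root1, 0});

    while (!stack.empty()) {
      NodeJob job = stack.back();
      stack.pop_back();
      const int n_node = job.end - job.start;
      if (n_node < 2 || job.n0 == 0 || job.n1 == 0) {
        tree.leaf_class[job.node_id] = job.n1 > job.n0 ? 1 : 0;
        continue;
      }
      const double parent = gini_n(job.n0, job.n1);
      for (int i = job.start; i < job.end; ++i) {
        node_y[i - job.start] = y_train[boot[i]];
      }

      // draw mtry features without replacement (partial Fisher-Yates)
      double best_gain = 1e-12;
      int best_f = -1, best_b = -1;
      int best_l0 = 0, best_l1 = 0;
      for (int j = 0; j < mtry; ++j) {
        const int swap_with = j + rng.below(p - j);
        std::swap(feat_pool[j], feat_pool[swap_with]);
        const int f = feat_pool[j];
        const int nb = static_cast<int>(edges[f].size());
        if (nb < 2) continue;
        const uint8_t* code = &bin_code[static_cast<size_t>(f) * n_train];

        if (n_node <= SMALL_NODE) {
          // pack (bin << 1 | label) and sort: O(n log n) beats scanning bins
          for (int i = 0; i < n_node; ++i) {
            small_buf[i] = static_cast<uint16_t>(
                (code[boot[job.start + i]] << 1) | node_y[i]);
          }
          std::sort(small_buf.begin(), small_buf.begin() + n_node);
          int l0 = 0, l1 = 0;
          for (int i = 0; i < n_node - 1; ++i) {
            if (small_buf[i] & 1) ++l1; else ++l0;
            if ((small_buf[i] >> 1) == (small_buf[i + 1] >> 1)) continue;
            const double gain =
                parent - gini_n(l0, l1) - gini_n(job.n0 - l0, job.n1 - l1);
            if (gain > best_gain) {
              best_gain = gain;
              best_f = f;
              best_b = small_buf[i] >> 1;
              best_l0 = l0;
              best_l1 = l1;
            }
          }
          continue;
        }

        int minb = 255, maxb = 0;
        for (int i = 0; i < n_node; ++i) {
          const int b = code[boot[job.start + i]];
          if (b < minb) minb = b;
          if (b > maxb) maxb = b;
          if (node_y[i] == 1) ++cnt1[b]; else ++cnt0[b];
        }
        if (minb < maxb) {
          int l0 = 0, l1 = 0;
          for (int b = minb; b < maxb; ++b) {
            l0 += cnt0[b];
            l1 += cnt1[b];
            const int l = l0 + l1;
            if (l == 0) continue;
            const double gain =
                parent - gini_n(l0, l1) - gini_n(job.n0 - l0, job.n1 - l1);
            if (gain > best_gain) {
              best_gain = gain;
              best_f = f;
              best_b = b;
              best_l0 = l0;
              best_l1 = l1;
            }
          }
        }
        for (int b = minb; b <= maxb; ++b) cnt0[b] = cnt1[b] = 0;
      }

      if (best_f < 0) {  // no impurity-reducing split among candidates
        tree.leaf_class[job.node_id] = job.n1 > job.n0 ? 1 : 0;
        continue;
      }

      // importance: impurity decrease weighted by node mass (Gini was
      // count-scaled already, so gain/n_bootstrap is the weighted decrease)
      tree_imp[best_f] += best_gain / n_train;

      const uint8_t* code = &bin_code[static_cast<size_t>(best_f) * n_train];
      const int thr_b = best_b;
      int* first = boot.data() + job.start;
      int* last = boot.data() + job.end;
      int* mid = std::partition(first, last,
                                [&](int i) { return code[i] <= thr_b; });
      const int n_left = static_cast<int>(mid - first);

      const int li = static_cast<int>(tree.feature.size());
      const int ri = li + 1;
      for (int k = 0; k < 2; ++k) {
        tree.feature.push_back(-1);
        tree.threshold.push_back(0.0);
        tree.left.push_back(-1);
        tree.right.push_back(-1);
        tree.leaf_class.push_back(0);
      }
      tree.feature[job.node_id] = best_f;
      tree.threshold[job.node_id] = edges[best_f][best_b];
      tree.left[job.node_id] = li;
      tree.right[job.node_id] = ri;
      stack.push_back({job.start, job.start + n_left, best_l0, best_l1, li});
      stack.push_back({job.start + n_left, job.end, job.n0 - best_l0,
                       job.n1 - best_l1, ri});
    }

    double imp_sum = 0.0;
    for (int f = 0; f < p; ++f) imp_sum += tree_imp[f];
    if (imp_sum > 0.0) {
      for (int f = 0; f < p; ++f) importance[f] += tree_imp[f] / imp_sum;
    }

    // vote on the evaluation rows with raw feature values
    for (int i = 0; i < n_eval; ++i) {
      const int row = eval_idx[i];
      int node = 0;
      while (tree.feature[node] >= 0) {
        node = (X(row, tree.feature[node]) <= tree.threshold[node])
                   ? tree.left[node]
                   : tree.right[node];
      }
      votes1[i] += tree.leaf_class[node];
    }
  }

  for (int f = 0; f < p; ++f) importance[f] /= n_trees;

  IntegerVector pred(n_eval);
  for (int i = 0; i < n_eval; ++i) {
    pred[i] = (2 * votes1[i] > n_trees) ? 1 : 0;  // tie -> negative class
  }

  return List::create(_["importance"] = importance, _["prediction"] = pred,
                      _["votes_high"] = IntegerVector(votes1.begin(), votes1.end()));
}
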