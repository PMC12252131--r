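// Path-dependent TreeSHAP for regression tree ensembles, plus the node
// routing needed to recompute per-node sample covers from training data.
//
// Trees arrive as parallel vectors (left/right child, split feature,
// threshold, leaf value, node cover); numeric splits send x <= threshold
// to the left child, matching the convention of the forests we consume.
// Attributions satisfy local accuracy: for every sample,
// base + sum(phi) equals the ensemble prediction.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *path, unsigned depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[depth].feature_index = feature_index;
  path[depth].zero_fraction = zero_fraction;
  path[depth].one_fraction = one_fraction;
  path[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = depth - 1; i >= 0; i--) {
    path[i + 1].pweight +=
        one_fraction * path[i].pweight * (i + 1) / (double)(depth + 1);
    path[i].pweight =
        zero_fraction * path[i].pweight * (depth - i) / (double)(depth + 1);
  }
}

static void unwind_path(PathElement *path, unsigned depth,
                        unsigned path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight =
          next_one_portion * (depth + 1) / (double)((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
                                   (depth - i) / (double)(depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (depth + 1)) /
                        (double)(zero_fraction * (depth - i));
    }
  }
  for (unsigned i = path_index; i < depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, unsigned depth,
                               unsigned path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[depth].pweight;
  double total = 0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp =
          next_one_portion * (depth + 1) / (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion =
          path[i].pweight -
          tmp * zero_fraction * ((depth - i) / (double)(depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
               ((depth - i) / (double)(depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void tree_shap_recurse(const Tree &tr, const double *x, double *phi,
                              unsigned node, unsigned depth,
                              PathElement *parent_path,
                              double parent_zero_fraction,
                              double parent_one_fraction,
                              int parent_feature_index) {
  PathElement *path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extend_path(path, depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);

  if (tr.feature[node] < 0) {  // leaf
    for (unsigned i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      const PathElement &el = path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tr.value[node];
    }
    return;
  }

  const int split = tr.feature[node];
  const unsigned hot =
      (x[split] <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  const unsigned cold =
      (x[split] <= tr.threshold[node]) ? tr.right[node] : tr.left[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = tr.cover[hot] / w;
  const double cold_zero_fraction = tr.cover[cold] / w;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  unsigned path_index = 0;
  for (; path_index <= depth; ++path_index) {
    if (path[path_index].feature_index == split) break;
  }
  if (path_index != depth + 1) {
    incoming_zero_fraction = path[path_index].zero_fraction;
    incoming_one_fraction = path[path_index].one_fraction;
    unwind_path(path, depth, path_index);
    depth -= 1;
  }

  tree_shap_recurse(tr, x, phi, hot, depth + 1, path,
                    hot_zero_fraction * incoming_zero_fraction,
                    incoming_one_fraction, split);
  tree_shap_recurse(tr, x, phi, cold, depth + 1, path,
                    cold_zero_fraction * incoming_zero_fraction, 0.0,
                    split);
}

static int tree_max_depth(const Tree &tr, int node, int depth) {
  if (tr.feature[node] < 0) return depth;
  int a = tree_max_depth(tr, tr.left[node], depth + 1);
  int b = tree_max_depth(tr, tr.right[node], depth + 1);
  return a > b ? a : b;
}

static Tree tree_from_list(const List &t) {
  Tree tr;
  tr.left = INTEGER(t["left"]);
  tr.right = INTEGER(t["right"]);
  tr.feature = INTEGER(t["feature"]);
  tr.threshold = REAL(t["threshold"]);
  tr.value = REAL(t["value"]);
  tr.cover = REAL(t["cover"]);
  return tr;
}

// Per-node sample counts obtained by routing every row of X through the
// tree (left on x <= threshold).
// [[Rcpp::export]]
NumericVector tree_cover_cpp(List tree, NumericMatrix X) {
  Tree tr = tree_from_list(tree);
  IntegerVector left = tree["left"];
  const int n_nodes = left.size();
  NumericVector cover(n_nodes);
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    for (;;) {
      cover[node] += 1.0;
      if (tr.feature[node] < 0) break;
      node = (X(i, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node]
                                                            : tr.right[node];
    }
  }
  return cover;
}

// Ensemble prediction (mean of per-tree leaf values).
// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int n_trees = trees.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feature[node] >= 0) {
        node = (X(i, tr.feature[node]) <= tr.threshold[node])
                   ? tr.left[node]
                   : tr.right[node];
      }
      out[i] += tr.value[node];
    }
  }
  return out / (double)n_trees;
}

// SHAP attributions for all samples, averaged over trees. The "base"
// attribute holds the ensemble expected value under the cover weights;
// base + rowSums(result) reproduces forest_predict_cpp.
// [[Rcpp::export]]
NumericMatrix forest_shap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  const int n_trees = trees.size();
  NumericMatrix phi(n, p);
  double base = 0;

  std::vector<double> xrow(p);
  for (int t = 0; t < n_trees; ++t) {
    List tl = trees[t];
    Tree tr = tree_from_list(tl);
    IntegerVector left = tl["left"];
    const int n_nodes = left.size();

    // cover-weighted expected value per node, leaves upward
    std::vector<double> expv(n_nodes, 0.0);
    for (int node = n_nodes - 1; node >= 0; --node) {
      if (tr.feature[node] < 0) {
        expv[node] = tr.value[node];
      } else {
        expv[node] = (expv[tr.left[node]] * tr.cover[tr.left[node]] +
                      expv[tr.right[node]] * tr.cover[tr.right[node]]) /
                     tr.cover[node];
      }
    }
    base += expv[0];

    const int maxd = tree_max_depth(tr, 0, 0) + 2;
    std::vector<PathElement> path((maxd * (maxd + 1)) / 2 + maxd);
    std::vector<double> phirow(p);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::fill(phirow.begin(), phirow.end(), 0.0);
      tree_shap_recurse(tr, xrow.data(), phirow.data(), 0, 0, path.data(),
                        1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phirow[j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= (double)n_trees;
  phi.attr("base") = base / (double)n_trees;
  return phi;
}
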