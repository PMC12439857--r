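// Double-precision tree traversal and TreeSHAP attributions for the
// gradient-boosted backend. The booster's own contribution predictor
// accumulates in single precision; recomputing from the dumped trees in
// double precision makes the additivity identity (base + sum(phi) = model
// output) hold to double-precision rounding, the same approach the reference
// SHAP implementation takes with its own tree traversal.
//
// Forest encoding (flattened, one entry per node):
//   feature[j]  split feature index, -1 for a leaf
//   threshold[j] split threshold (x < threshold goes to `yes`)
//   yes[j], no[j], missing[j]  absolute child indices (-1 for leaves)
//   value[j]    leaf value (0 for internal nodes)
//   cover[j]    training sample weight reaching the node
//   tree_root[t] index of tree t's root

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

void extend_path(PathElement *unique_path, int unique_depth,
                 double zero_fraction, double one_fraction, int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
      (i + 1) / static_cast<double>(unique_depth + 1);
    unique_path[i].pweight *= zero_fraction * (unique_depth - i) /
      static_cast<double>(unique_depth + 1);
  }
}

void unwind_path(PathElement *unique_path, int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;

  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
        (unique_depth - i) / static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
        static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction *
        ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
        ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct Forest {
  const int *feature;
  const double *threshold;
  const int *yes;
  const int *no_;
  const int *missing;
  const double *value;
  const double *cover;
};

int next_node(const Forest &f, int j, double x) {
  if (ISNAN(x)) return f.missing[j];
  // the backend stores features and thresholds in single precision; replicate
  // its comparison exactly so both traversals select the same leaf
  return static_cast<float>(x) < static_cast<float>(f.threshold[j])
    ? f.yes[j] : f.no_[j];
}

void tree_shap_recursive(const Forest &f, const double *x, double *phi,
                         int node, int unique_depth,
                         PathElement *parent_unique_path,
                         double parent_zero_fraction,
                         double parent_one_fraction,
                         int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1, unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (f.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
        w * (el.one_fraction - el.zero_fraction) * f.value[node];
    }
    return;
  }

  const int split_feature = f.feature[node];
  const int hot = next_node(f, node, x[split_feature]);
  const int cold = hot == f.yes[node] ? f.no_[node] : f.yes[node];
  const double w_node = f.cover[node];
  const double hot_zero_fraction = f.cover[hot] / w_node;
  const double cold_zero_fraction = f.cover[cold] / w_node;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  // if this feature was already split on upstream, undo that path entry
  int path_index = 1;
  while (path_index <= unique_depth &&
         unique_path[path_index].feature_index != split_feature) {
    ++path_index;
  }
  if (path_index <= unique_depth) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    --unique_depth;
  }

  tree_shap_recursive(f, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(f, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction,
                      0.0, split_feature);
}

int tree_max_depth(const Forest &f, int node) {
  if (f.feature[node] < 0) return 0;
  const int a = tree_max_depth(f, f.yes[node]);
  const int b = tree_max_depth(f, f.no_[node]);
  return 1 + (a > b ? a : b);
}

double tree_expected_value(const Forest &f, int node) {
  if (f.feature[node] < 0) return f.value[node];
  const double w = f.cover[node];
  return (f.cover[f.yes[node]] / w) * tree_expected_value(f, f.yes[node]) +
         (f.cover[f.no_[node]] / w) * tree_expected_value(f, f.no_[node]);
}

Forest make_forest(const IntegerVector &feature, const NumericVector &threshold,
                   const IntegerVector &yes, const IntegerVector &no,
                   const IntegerVector &missing, const NumericVector &value,
                   const NumericVector &cover) {
  Forest f;
  f.feature = feature.begin();
  f.threshold = threshold.begin();
  f.yes = yes.begin();
  f.no_ = no.begin();
  f.missing = missing.begin();
  f.value = value.begin();
  f.cover = cover.begin();
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".forest_predict_cpp")]]
NumericVector forest_predict_cpp(NumericMatrix x, IntegerVector feature,
                                 NumericVector threshold, IntegerVector yes,
                                 IntegerVector no, IntegerVector missing,
                                 NumericVector value, NumericVector cover,
                                 IntegerVector tree_root, double base_score) {
  const Forest f = make_forest(feature, threshold, yes, no, missing, value, cover);
  const int n = x.nrow();
  NumericVector out(n, base_score);
  std::vector<double> row(x.ncol());
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < x.ncol(); ++c) row[c] = x(r, c);
    double s = 0;
    for (int t = 0; t < tree_root.size(); ++t) {
      int j = tree_root[t];
      while (f.feature[j] >= 0) j = next_node(f, j, row[f.feature[j]]);
      s += f.value[j];
    }
    out[r] += s;
  }
  return out;
}

// [[Rcpp::export(name = ".forest_treeshap_cpp")]]
NumericMatrix forest_treeshap_cpp(NumericMatrix x, IntegerVector feature,
                                  NumericVector threshold, IntegerVector yes,
                                  IntegerVector no, IntegerVector missing,
                                  NumericVector value, NumericVector cover,
                                  IntegerVector tree_root, double base_score) {
  const Forest f = make_forest(feature, threshold, yes, no, missing, value, cover);
  const int n = x.nrow();
  const int p = x.ncol();
  const int n_trees = tree_root.size();
  NumericMatrix phi(n, p + 1);  // last column: expected value (intercept)

  int max_d = 0;
  double base_total = base_score;
  std::vector<double> expected(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    const int d = tree_max_depth(f, tree_root[t]);
    if (d > max_d) max_d = d;
    expected[t] = tree_expected_value(f, tree_root[t]);
    base_total += expected[t];
  }
  // arena for the unique paths along one root-to-leaf recursion
  const int arena = (max_d + 2) * (max_d + 3) / 2 + 1;
  std::vector<PathElement> path(arena);
  std::vector<double> row(p);
  std::vector<double> phirow(p);

  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < p; ++c) row[c] = x(r, c);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    for (int t = 0; t < n_trees; ++t) {
      if (f.feature[tree_root[t]] < 0) continue;  // stump: all in base value
      tree_shap_recursive(f, row.data(), phirow.data(), tree_root[t], 0,
                          path.data(), 1.0, 1.0, -1);
    }
    for (int c = 0; c < p; ++c) phi(r, c) = phirow[c];
    phi(r, p) = base_total;
  }
  return phi;
}
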