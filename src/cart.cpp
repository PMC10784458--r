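// CART core for the state classifier: classification trees (Gini) grown on
// bootstrap samples with per-node feature subsampling (random forest), and
// squared-error regression trees with Newton leaf updates (gradient-boosted
// trees, logistic loss). Trees are returned as flat parallel arrays so the R
// side can serialize them and walk decision paths.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct FlatTree {
  std::vector<int> feature;      // split feature (0-based), -1 at leaves
  std::vector<double> threshold; // go left iff x <= threshold
  std::vector<int> left, right;  // child node ids, -1 at leaves
  std::vector<double> value;     // class-1 fraction (clf) or leaf value (reg)
  std::vector<int> n_node;       // training rows reaching the node

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    n_node.push_back(0);
    return (int)feature.size() - 1;
  }
};

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// Grows one tree over the rows in `rows`. `yc` is 0/1 for classification;
// `yr` is the regression target (used when classify == false). `hess`
// (optional, same length as yr) drives Newton leaf values for boosting.
class Grower {
public:
  Grower(const NumericMatrix& X, const IntegerVector& yc,
         const NumericVector& yr, const NumericVector& hess,
         bool classify, int mtry, int max_depth, int min_split, int min_leaf,
         std::mt19937& rng, std::vector<double>& importance)
    : X_(X), yc_(yc), yr_(yr), hess_(hess), classify_(classify),
      mtry_(mtry), max_depth_(max_depth), min_split_(min_split),
      min_leaf_(min_leaf), rng_(rng), importance_(importance) {
    p_ = X_.ncol();
    feat_order_.resize(p_);
    for (int j = 0; j < p_; ++j) feat_order_[j] = j;
  }

  FlatTree grow(std::vector<int> rows) {
    tree_ = FlatTree();
    n_root_ = (int)rows.size();
    build(std::move(rows), 0);
    return tree_;
  }

private:
  double node_impurity(const std::vector<int>& rows, double& mean_out) const {
    int n = (int)rows.size();
    if (classify_) {
      int n1 = 0;
      for (int r : rows) n1 += yc_[r];
      double p1 = (double)n1 / n;
      mean_out = p1;
      return 2.0 * p1 * (1.0 - p1); // Gini
    }
    double s = 0.0, s2 = 0.0;
    for (int r : rows) { s += yr_[r]; s2 += yr_[r] * yr_[r]; }
    double m = s / n;
    mean_out = m;
    return s2 / n - m * m; // variance
  }

  double leaf_value(const std::vector<int>& rows, double mean) const {
    if (classify_ || hess_.size() == 0) return mean;
    // Newton step for logistic boosting: sum(grad) / sum(hess)
    double sg = 0.0, sh = 0.0;
    for (int r : rows) { sg += yr_[r]; sh += hess_[r]; }
    return sg / (sh + 1e-12);
  }

  Split best_split(const std::vector<int>& rows, double imp_node) {
    int n = (int)rows.size();
    Split best;
    int ntry = std::min(mtry_, p_);
    // partial Fisher-Yates over the persistent feature order
    for (int j = 0; j < ntry; ++j) {
      std::uniform_int_distribution<int> d(j, p_ - 1);
      std::swap(feat_order_[j], feat_order_[d(rng_)]);
    }
    std::vector<std::pair<double, int>> xv(n);
    for (int j = 0; j < ntry; ++j) {
      int f = feat_order_[j];
      for (int i = 0; i < n; ++i) xv[i] = { X_(rows[i], f), rows[i] };
      std::sort(xv.begin(), xv.end());
      if (xv.front().first >= xv.back().first) continue; // constant
      if (classify_) {
        int n1l = 0;
        int n1 = 0;
        for (int i = 0; i < n; ++i) n1 += yc_[xv[i].second];
        for (int i = 0; i < n - 1; ++i) {
          n1l += yc_[xv[i].second];
          if (xv[i].first >= xv[i + 1].first) continue;
          int nl = i + 1, nr = n - nl;
          if (nl < min_leaf_ || nr < min_leaf_) continue;
          double pl = (double)n1l / nl, pr = (double)(n1 - n1l) / nr;
          double child = (nl * 2.0 * pl * (1 - pl) + nr * 2.0 * pr * (1 - pr)) / n;
          double gain = imp_node - child;
          if (gain > best.gain + 1e-12) {
            best.feature = f;
            best.threshold = 0.5 * (xv[i].first + xv[i + 1].first);
            best.gain = gain;
          }
        }
      } else {
        double sl = 0.0, s = 0.0, s2 = 0.0;
        for (int i = 0; i < n; ++i) {
          double v = yr_[xv[i].second];
          s += v; s2 += v * v;
        }
        for (int i = 0; i < n - 1; ++i) {
          sl += yr_[xv[i].second];
          if (xv[i].first >= xv[i + 1].first) continue;
          int nl = i + 1, nr = n - nl;
          if (nl < min_leaf_ || nr < min_leaf_) continue;
          double sr = s - sl;
          // variance reduction up to constants: imp - (ssl/n ... ) use
          // standard proxy: sum sq deviations
          double child = (s2 - sl * sl / nl - sr * sr / nr) / n;
          double parent = s2 / n - (s / n) * (s / n);
          double gain = parent - child;
          if (gain > best.gain + 1e-12) {
            best.feature = f;
            best.threshold = 0.5 * (xv[i].first + xv[i + 1].first);
            best.gain = gain;
          }
        }
      }
    }
    (void)imp_node;
    return best;
  }

  int build(std::vector<int> rows, int depth) {
    int id = tree_.new_node();
    int n = (int)rows.size();
    tree_.n_node[id] = n;
    double mean;
    double imp = node_impurity(rows, mean);
    tree_.value[id] = leaf_value(rows, mean);
    bool stop = n < min_split_ || imp <= 1e-12 ||
                (max_depth_ > 0 && depth >= max_depth_);
    if (!stop) {
      Split sp = best_split(rows, imp);
      if (sp.feature >= 0) {
        importance_[sp.feature] += sp.gain * (double)n / (double)n_root_;
        std::vector<int> lrows, rrows;
        lrows.reserve(n); rrows.reserve(n);
        for (int r : rows) {
          if (X_(r, sp.feature) <= sp.threshold) lrows.push_back(r);
          else rrows.push_back(r);
        }
        rows.clear(); rows.shrink_to_fit();
        tree_.feature[id] = sp.feature;
        tree_.threshold[id] = sp.threshold;
        int l = build(std::move(lrows), depth + 1);
        int r = build(std::move(rrows), depth + 1);
        tree_.left[id] = l;
        tree_.right[id] = r;
      }
    }
    return id;
  }

  const NumericMatrix& X_;
  const IntegerVector& yc_;
  const NumericVector& yr_;
  const NumericVector& hess_;
  bool classify_;
  int mtry_, max_depth_, min_split_, min_leaf_, p_, n_root_ = 0;
  std::mt19937& rng_;
  std::vector<double>& importance_;
  FlatTree tree_;
  std::vector<int> feat_order_;
};

List tree_to_list(const FlatTree& t) {
  return List::create(
    _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
    _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
    _["left"] = IntegerVector(t.left.begin(), t.left.end()),
    _["right"] = IntegerVector(t.right.begin(), t.right.end()),
    _["value"] = NumericVector(t.value.begin(), t.value.end()),
    _["n_node"] = IntegerVector(t.n_node.begin(), t.n_node.end()));
}

double apply_tree(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericVector value = tree["value"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return value[node];
}

} // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int ntrees, int mtry,
                     int max_depth, int min_split, int min_leaf, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::vector<double> importance(p, 0.0);
  NumericVector dummy;
  List trees(ntrees);
  std::uniform_int_distribution<int> draw(0, n - 1);
  for (int t = 0; t < ntrees; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = draw(rng);
    Grower g(X, y, dummy, dummy, true, mtry, max_depth, min_split, min_leaf,
             rng, importance);
    trees[t] = tree_to_list(g.grow(std::move(rows)));
  }
  double tot = 0.0;
  for (double v : importance) tot += v;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector cpp_forest_score(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += apply_tree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, IntegerVector y, int nrounds,
                 double learning_rate, int max_depth, int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  double p1 = 0.0;
  for (int i = 0; i < n; ++i) p1 += y[i];
  p1 /= n;
  p1 = std::min(std::max(p1, 1e-6), 1.0 - 1e-6);
  double f0 = std::log(p1 / (1.0 - p1));
  std::vector<double> F(n, f0);
  std::vector<double> importance(p, 0.0);
  std::mt19937 rng(0); // unused: all features considered, no subsampling
  List trees(nrounds);
  NumericVector grad(n), hess(n);
  IntegerVector ydummy;
  for (int m = 0; m < nrounds; ++m) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      grad[i] = y[i] - pr;
      hess[i] = pr * (1.0 - pr);
    }
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    Grower g(X, ydummy, grad, hess, false, p, max_depth, 2, min_leaf, rng,
             importance);
    List tree = tree_to_list(g.grow(std::move(rows)));
    for (int i = 0; i < n; ++i)
      F[i] += learning_rate * apply_tree(tree, X, i);
    trees[m] = tree;
  }
  double tot = 0.0;
  for (double v : importance) tot += v;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = tot > 0 ? importance[j] / tot : 0.0;
  return List::create(_["trees"] = trees, _["f0"] = f0,
                      _["learning_rate"] = learning_rate,
                      _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector cpp_gbt_score(List model, NumericMatrix X) {
  List trees = model["trees"];
  double f0 = model["f0"];
  double lr = model["learning_rate"];
  int n = X.nrow(), T = trees.size();
  NumericVector out(n, f0);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += lr * apply_tree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
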