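#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <vector>

using namespace Rcpp;

// Depth-capped binary trees with case weights, used as boosting base
// learners. Determinism contract:
//   * split thresholds are midpoints between consecutive distinct sorted
//     feature values;
//   * ties between candidate splits are broken toward the lowest variable
//     index, then the lowest threshold;
//   * routing sends x_j <= t to the left child;
//   * weighted-majority ties at classification leaves go to class 1.
// Samples with zero weight are dropped before fitting, so they influence
// neither split choice nor leaf values.
//
// Each feature's sample order is sorted once up front; at every split the
// sorted lists are partitioned into the children, so node-level split
// search is a linear scan (no per-node sorting). Tie order within equal
// feature values is irrelevant: candidate boundaries exist only where the
// value changes.

namespace {

struct Node {
  int feature;      // 0-based feature index, -1 for leaf
  double threshold; // NA for leaf
  int left, right;  // 0-based node indices, -1 for leaf
  double value;     // leaf prediction (class 1/2 or weighted mean)
};

typedef std::vector<std::vector<int>> FeatureOrders;

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth, min_split, min_leaf;
  bool classify;
  std::vector<Node> nodes;
  std::set<int> used;
  int depth_reached = 0;

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const NumericVector& w_, int md, int ms, int ml, bool cls)
      : X(X_), y(y_), w(w_), max_depth(md), min_split(ms), min_leaf(ml),
        classify(cls) {}

  // ord[j] holds the node's sample indices sorted by feature j.
  int build(FeatureOrders& ord, int depth, double parent_value) {
    const int n = (int)ord[0].size();
    double W = 0.0, S = 0.0, S2 = 0.0, W1 = 0.0, W2 = 0.0;
    for (int i : ord[0]) {
      W += w[i];
      if (classify) {
        if (y[i] == 1.0) W1 += w[i]; else W2 += w[i];
      } else {
        S += w[i] * y[i];
        S2 += w[i] * y[i] * y[i];
      }
    }
    double value;
    if (W <= 0.0) {
      value = parent_value;
    } else if (classify) {
      value = (W2 > W1) ? 2.0 : 1.0;
    } else {
      value = S / W;
    }
    if (depth > depth_reached) depth_reached = depth;

    bool pure;
    double parent_score;
    if (classify) {
      pure = (W1 <= 0.0 || W2 <= 0.0);
      parent_score = (W > 0.0) ? (W1 * W1 + W2 * W2) / W : 0.0;
    } else {
      double sse = S2 - (W > 0.0 ? S * S / W : 0.0);
      pure = (sse <= 1e-12 * std::max(1.0, S2));
      parent_score = (W > 0.0) ? S * S / W : 0.0;
    }

    int self = (int)nodes.size();
    nodes.push_back({-1, NA_REAL, -1, -1, value});
    if (depth >= max_depth || n < min_split || pure || W <= 0.0)
      return self;

    // exhaustive search over features x thresholds on the sorted lists
    const double tol = 1e-12 * std::max(1.0, W);
    int best_feat = -1;
    double best_thr = NA_REAL, best_score = parent_score;
    const int p = X.ncol();
    for (int j = 0; j < p; ++j) {
      const std::vector<int>& oj = ord[j];
      double L1 = 0.0, L2 = 0.0, SL = 0.0, WL = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        int i = oj[k];
        WL += w[i];
        if (classify) {
          if (y[i] == 1.0) L1 += w[i]; else L2 += w[i];
        } else {
          SL += w[i] * y[i];
        }
        double xk = X(i, j), xk1 = X(oj[k + 1], j);
        if (xk1 <= xk) continue; // not a boundary
        if (k + 1 < min_leaf || n - k - 1 < min_leaf) continue;
        double WR = W - WL, score;
        if (classify) {
          double sl = (WL > 0.0) ? (L1 * L1 + L2 * L2) / WL : 0.0;
          double sr = (WR > 0.0) ? ((W1 - L1) * (W1 - L1) +
                                    (W2 - L2) * (W2 - L2)) / WR
                                 : 0.0;
          score = sl + sr;
        } else {
          double sl = (WL > 0.0) ? SL * SL / WL : 0.0;
          double SR = S - SL;
          double sr = (WR > 0.0) ? SR * SR / WR : 0.0;
          score = sl + sr;
        }
        if (score > best_score + tol) {
          best_score = score;
          best_feat = j;
          best_thr = (xk + xk1) / 2.0;
        }
      }
    }
    if (best_feat < 0) return self;

    used.insert(best_feat);
    // partition every feature's sorted list into the children
    FeatureOrders lord(p), rord(p);
    for (int j = 0; j < p; ++j) {
      lord[j].reserve(n);
      rord[j].reserve(n);
      for (int i : ord[j])
        (X(i, best_feat) <= best_thr ? lord[j] : rord[j]).push_back(i);
    }
    FeatureOrders().swap(ord); // release before recursing
    nodes[self].feature = best_feat;
    nodes[self].threshold = best_thr;
    int l = build(lord, depth + 1, value);
    FeatureOrders().swap(lord);
    int r = build(rord, depth + 1, value);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

inline double route(const IntegerVector& feature,
                    const NumericVector& threshold,
                    const IntegerVector& left, const IntegerVector& right,
                    const NumericVector& value, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (feature[node] > 0) {
    node = (X(row, feature[node] - 1) <= threshold[node]) ? left[node] - 1
                                                          : right[node] - 1;
  }
  return value[node];
}

} // namespace

// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, int min_samples_split, int min_samples_leaf,
                  bool classification) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> idx;
  idx.reserve(n);
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] < 0.0) stop("negative case weight");
    if (w[i] > 0.0) {
      idx.push_back(i);
      wsum += w[i];
    }
  }
  if (idx.empty() || wsum <= 0.0) stop("all case weights are zero");

  // one sort per feature; children inherit partitioned orders
  FeatureOrders ord(p, idx);
  for (int j = 0; j < p; ++j) {
    const double* col = X.begin() + (std::size_t)j * n;
    std::sort(ord[j].begin(), ord[j].end(),
              [col](int a, int b) { return col[a] < col[b]; });
  }

  Builder b(X, y, w, max_depth, min_samples_split, min_samples_leaf,
            classification);
  double fallback;
  if (classification) {
    double W1 = 0.0, W2 = 0.0;
    for (int i : idx) (y[i] == 1.0 ? W1 : W2) += w[i];
    fallback = (W2 > W1) ? 2.0 : 1.0;
  } else {
    double S = 0.0;
    for (int i : idx) S += w[i] * y[i];
    fallback = S / wsum;
  }
  b.build(ord, 0, fallback);

  const int m = (int)b.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int k = 0; k < m; ++k) {
    // 1-based ids on the R side; -1 marks "none"
    feature[k] = b.nodes[k].feature >= 0 ? b.nodes[k].feature + 1 : -1;
    threshold[k] = b.nodes[k].threshold;
    left[k] = b.nodes[k].left >= 0 ? b.nodes[k].left + 1 : -1;
    right[k] = b.nodes[k].right >= 0 ? b.nodes[k].right + 1 : -1;
    value[k] = b.nodes[k].value;
  }
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold, _["left"] = left,
      _["right"] = right, _["value"] = value, _["depth"] = b.depth_reached,
      _["n_variables_used"] = (int)b.used.size());
}

// [[Rcpp::export]]
NumericVector predict_tree_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = route(feature, threshold, left, right, value, X, i);
  return out;
}

// Per-stage raw tree outputs for a whole ensemble: n x M matrix, one pass.
// [[Rcpp::export]]
NumericMatrix predict_stages_cpp(List trees, NumericMatrix X) {
  const int M = trees.size(), n = X.nrow();
  NumericMatrix out(n, M);
  for (int m = 0; m < M; ++m) {
    List t = trees[m];
    IntegerVector feature = t["feature"], left = t["left"],
                  right = t["right"];
    NumericVector threshold = t["threshold"], value = t["value"];
    for (int i = 0; i < n; ++i)
      out(i, m) = route(feature, threshold, left, right, value, X, i);
  }
  return out;
}
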