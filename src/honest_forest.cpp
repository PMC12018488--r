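// Honest weighted regression-tree ensemble backing the reference T-learner.
// Each tree is grown on a bootstrap draw whose first half chooses splits
// (weighted squared-error reduction, exhaustive threshold scan) and whose
// second half supplies the leaf means (honesty). Trees are grown to purity
// subject to a minimum leaf size; no depth cap.
//
// All randomness (bootstrap indices) is drawn in R and passed in, so the
// ensemble is reproducible from a single R seed.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <numeric>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;        // -1 for leaf
  double threshold = 0.0;  // go left iff x[feature] <= threshold
  int left = -1, right = -1;
  double value = 0.0;      // estimation-sample weighted mean
};

struct Problem {
  const double* X;  // column-major n x p
  const double* y;
  const double* w;
  int n, p;
  int min_leaf;
  double col(int i, int j) const { return X[(size_t)j * n + i]; }
};

struct BestSplit {
  int feature = -1;
  double threshold = 0.0;
  double reduction = 0.0;
};

// Exhaustive best split over all features for the rows in `idx` (split
// sample). Deterministic tie-break: larger reduction, then lower feature
// index, then lower threshold (the scan visits thresholds in increasing
// order per feature, so the first strict improvement wins).
BestSplit find_best_split(const Problem& prob, std::vector<int>& idx,
                          std::vector<int>& scratch) {
  BestSplit best;
  const int m = (int)idx.size();
  if (m < 2 * prob.min_leaf) return best;

  double wtot = 0.0, wytot = 0.0;
  for (int i : idx) { wtot += prob.w[i]; wytot += prob.w[i] * prob.y[i]; }
  if (wtot <= 0.0) return best;
  const double parent_sse_term = wytot * wytot / wtot;

  scratch.resize(m);
  for (int j = 0; j < prob.p; ++j) {
    // sort row indices by feature value (stable not needed: reduction only
    // depends on the multiset split, and ties across equal values are not
    // admissible thresholds)
    std::copy(idx.begin(), idx.end(), scratch.begin());
    std::sort(scratch.begin(), scratch.end(), [&](int a, int b) {
      return prob.col(a, j) < prob.col(b, j);
    });
    double wl = 0.0, wyl = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      const int i = scratch[k];
      wl += prob.w[i];
      wyl += prob.w[i] * prob.y[i];
      const double xk = prob.col(i, j);
      const double xk1 = prob.col(scratch[k + 1], j);
      if (xk1 <= xk) continue;               // no boundary between equal values
      if (k + 1 < prob.min_leaf || m - k - 1 < prob.min_leaf) continue;
      const double wr = wtot - wl, wyr = wytot - wyl;
      if (wl <= 0.0 || wr <= 0.0) continue;
      const double red = wyl * wyl / wl + wyr * wyr / wr - parent_sse_term;
      if (red > best.reduction + 1e-12) {
        best.feature = j;
        best.threshold = 0.5 * (xk + xk1);
        best.reduction = red;
      }
    }
  }
  return best;
}

void grow(const Problem& prob, std::vector<Node>& nodes, int node_id,
          std::vector<int> split_idx, std::vector<int> est_idx,
          double parent_value, std::vector<int>& scratch) {
  // leaf value from the estimation sample; fall back to the parent's value
  // when honesty leaves the node empty
  double wsum = 0.0, wysum = 0.0;
  for (int i : est_idx) { wsum += prob.w[i]; wysum += prob.w[i] * prob.y[i]; }
  const double value = (wsum > 0.0) ? wysum / wsum : parent_value;
  nodes[node_id].value = value;

  BestSplit bs = find_best_split(prob, split_idx, scratch);
  if (bs.feature < 0) return;  // leaf

  std::vector<int> sl, sr, el, er;
  sl.reserve(split_idx.size()); sr.reserve(split_idx.size());
  for (int i : split_idx) {
    (prob.col(i, bs.feature) <= bs.threshold ? sl : sr).push_back(i);
  }
  el.reserve(est_idx.size()); er.reserve(est_idx.size());
  for (int i : est_idx) {
    (prob.col(i, bs.feature) <= bs.threshold ? el : er).push_back(i);
  }

  nodes[node_id].feature = bs.feature;
  nodes[node_id].threshold = bs.threshold;
  const int li = (int)nodes.size(); nodes.emplace_back();
  const int ri = (int)nodes.size(); nodes.emplace_back();
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow(prob, nodes, li, std::move(sl), std::move(el), value, scratch);
  grow(prob, nodes, ri, std::move(sr), std::move(er), value, scratch);
}

}  // namespace

// [[Rcpp::export(name = ".hf_grow")]]
List hf_grow(NumericMatrix X, NumericVector y, NumericVector w,
             IntegerMatrix boot, bool honest, int min_leaf) {
  const int n = X.nrow();
  Problem prob{REAL(X), REAL(y), REAL(w), n, X.ncol(), min_leaf};
  const int B = boot.ncol();
  List forest(B);
  std::vector<int> scratch;

  for (int b = 0; b < B; ++b) {
    std::vector<int> draw(boot.nrow());
    for (int k = 0; k < boot.nrow(); ++k) {
      const int i = boot(k, b) - 1;  // R is 1-based
      if (i < 0 || i >= n) stop("bootstrap index out of range");
      draw[k] = i;
    }
    std::vector<int> split_idx, est_idx;
    if (honest) {
      const int half = (int)draw.size() / 2;
      split_idx.assign(draw.begin(), draw.begin() + half);
      est_idx.assign(draw.begin() + half, draw.end());
    } else {
      split_idx = draw;
      est_idx = draw;
    }
    double wsum = 0.0, wysum = 0.0;
    for (int i : est_idx) { wsum += prob.w[i]; wysum += prob.w[i] * prob.y[i]; }
    const double root_fallback = (wsum > 0.0) ? wysum / wsum : 0.0;

    std::vector<Node> nodes;
    nodes.emplace_back();
    grow(prob, nodes, 0, std::move(split_idx), std::move(est_idx),
         root_fallback, scratch);

    const int m = (int)nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), value(m);
    for (int k = 0; k < m; ++k) {
      feature[k] = nodes[k].feature;
      threshold[k] = nodes[k].threshold;
      left[k] = nodes[k].left;
      right[k] = nodes[k].right;
      value[k] = nodes[k].value;
    }
    forest[b] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                             _["left"] = left, _["right"] = right,
                             _["value"] = value);
  }
  return forest;
}

// [[Rcpp::export(name = ".hf_predict")]]
NumericVector hf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int B = forest.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    List tree = forest[b];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector threshold = tree["threshold"], value = tree["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += value[node];
    }
  }
  if (B > 0) out = out / (double)B;
  return out;
}
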