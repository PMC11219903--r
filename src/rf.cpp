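#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Random Forest for classification: bagged CART trees with Gini splits and
// mtry random candidate features per node. Uses R's RNG (so set.seed()
// controls bootstrap and feature subsampling) and deterministic tie-breaks
// (lowest class code), single-threaded for cross-platform reproducibility.

namespace {

struct TreeBuf {
  std::vector<int> feat, left, right, pred;
  std::vector<double> thresh;
};

int majority(const std::vector<int>& counts) {
  int best = 0, bc = -1;
  for (size_t k = 0; k < counts.size(); ++k) {
    if (counts[k] > bc) { bc = counts[k]; best = (int)k; }
  }
  return best + 1;  // class codes are 1-based; ties fall to lowest code
}

// Build one node over rows idx[lo..hi); returns node id.
int build_node(TreeBuf& T, const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int lo, int hi, int K, int mtry,
               int min_node, std::vector<int>& featbuf,
               std::vector<std::pair<double,int>>& sortbuf) {
  int node = (int)T.feat.size();
  T.feat.push_back(-1); T.thresh.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1); T.pred.push_back(0);
  int n = hi - lo;
  std::vector<int> counts(K, 0);
  for (int t = lo; t < hi; ++t) counts[y[idx[t]] - 1]++;
  int nz = 0;
  for (int k = 0; k < K; ++k) if (counts[k] > 0) ++nz;
  if (nz <= 1 || n <= min_node) {
    T.pred[node] = majority(counts);
    return node;
  }
  int p = X.ncol();
  // random feature order (full Fisher-Yates); the first mtry features are
  // the candidate set, but if none of them admits a valid split the search
  // continues down the permutation (as ranger-style forests do) so constant
  // candidates do not force a premature leaf
  for (int k = 0; k < p; ++k) featbuf[k] = k;
  int m = std::min(mtry, p);
  for (int k = 0; k < p - 1; ++k) {
    int r = k + (int)(unif_rand() * (p - k));
    if (r >= p) r = p - 1;
    std::swap(featbuf[k], featbuf[r]);
  }
  double best_gini = R_PosInf, best_thr = 0.0;
  int best_feat = -1;
  for (int k = 0; k < p; ++k) {
    if (k >= m && best_feat >= 0) break;
    int f = featbuf[k];
    sortbuf.clear();
    for (int t = lo; t < hi; ++t)
      sortbuf.push_back(std::make_pair(X(idx[t], f), y[idx[t]]));
    std::sort(sortbuf.begin(), sortbuf.end());
    if (sortbuf.front().first == sortbuf.back().first) continue;
    std::vector<int> leftc(K, 0);
    std::vector<int> rightc(counts);
    for (int t = 0; t < n - 1; ++t) {
      int cls = sortbuf[t].second - 1;
      leftc[cls]++; rightc[cls]--;
      if (sortbuf[t].first == sortbuf[t + 1].first) continue;
      double nl = t + 1.0, nr_ = n - t - 1.0;
      double gl = 1.0, gr = 1.0;
      for (int c = 0; c < K; ++c) {
        double pl = leftc[c] / nl, pr = rightc[c] / nr_;
        gl -= pl * pl; gr -= pr * pr;
      }
      double g = (nl * gl + nr_ * gr) / n;
      if (g < best_gini) {
        best_gini = g;
        best_feat = f;
        best_thr = 0.5 * (sortbuf[t].first + sortbuf[t + 1].first);
      }
    }
  }
  if (best_feat < 0) {  // all sampled features constant on this node
    T.pred[node] = majority(counts);
    return node;
  }
  // partition idx[lo..hi) stably by the split
  std::vector<int> lpart, rpart;
  for (int t = lo; t < hi; ++t) {
    if (X(idx[t], best_feat) <= best_thr) lpart.push_back(idx[t]);
    else rpart.push_back(idx[t]);
  }
  if (lpart.empty() || rpart.empty()) {
    T.pred[node] = majority(counts);
    return node;
  }
  for (size_t t = 0; t < lpart.size(); ++t) idx[lo + t] = lpart[t];
  for (size_t t = 0; t < rpart.size(); ++t) idx[lo + lpart.size() + t] = rpart[t];
  T.feat[node] = best_feat;
  T.thresh[node] = best_thr;
  int mid = lo + (int)lpart.size();
  T.left[node] = build_node(T, X, y, idx, lo, mid, K, mtry, min_node,
                            featbuf, sortbuf);
  T.right[node] = build_node(T, X, y, idx, mid, hi, K, mtry, min_node,
                             featbuf, sortbuf);
  return node;
}

struct TreeView {
  IntegerVector feat, left, right, pred;
  NumericVector thresh;
  explicit TreeView(const List& tree)
      : feat(tree["feat"]), left(tree["left"]), right(tree["right"]),
        pred(tree["pred"]), thresh(tree["thresh"]) {}
};

int predict_row(const TreeView& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feat[node] >= 0) {
    node = (X(row, t.feat[node]) <= t.thresh[node]) ? t.left[node]
                                                    : t.right[node];
  }
  return t.pred[node];
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int K, int ntree,
                  int mtry, int min_node) {
  int n = X.nrow();
  List trees(ntree);
  IntegerMatrix oob_votes(n, K);
  std::vector<int> featbuf(X.ncol());
  std::vector<std::pair<double,int>> sortbuf;
  for (int tr = 0; tr < ntree; ++tr) {
    std::vector<int> idx(n);
    std::vector<bool> inbag(n, false);
    for (int t = 0; t < n; ++t) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[t] = r;
      inbag[r] = true;
    }
    TreeBuf T;
    build_node(T, X, y, idx, 0, n, K, mtry, min_node, featbuf, sortbuf);
    List tree = List::create(
      _["feat"] = wrap(T.feat), _["thresh"] = wrap(T.thresh),
      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
      _["pred"] = wrap(T.pred));
    trees[tr] = tree;
    TreeView tv(tree);
    for (int r = 0; r < n; ++r) {
      if (!inbag[r]) {
        int cls = predict_row(tv, X, r);
        oob_votes(r, cls - 1)++;
      }
    }
  }
  return List::create(_["trees"] = trees, _["oob_votes"] = oob_votes);
}

// [[Rcpp::export]]
IntegerMatrix cpp_rf_votes(List trees, NumericMatrix X, int K) {
  int n = X.nrow();
  IntegerMatrix votes(n, K);
  for (int tr = 0; tr < trees.size(); ++tr) {
    List tree = trees[tr];
    TreeView tv(tree);
    for (int r = 0; r < n; ++r) {
      int cls = predict_row(tv, X, r);
      votes(r, cls - 1)++;
    }
  }
  return votes;
}
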