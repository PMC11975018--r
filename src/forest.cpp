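#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Compact classification random forest: CART trees with Gini splits grown on
// bootstrap samples, mtry candidate features per node, majority vote over
// trees. Randomness comes from the R RNG, so results are reproducible under
// set.seed() on the R side.

namespace {

struct Tree {
  std::vector<int> feat;      // split feature, -1 for leaf
  std::vector<double> thr;    // split threshold (x <= thr goes left)
  std::vector<int> left, right, pred;
};

double gini_impurity(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : counts) { double p = (double)c / n; s += p * p; }
  return 1.0 - s;
}

int majority(const std::vector<int>& counts) {
  int best = 0;
  for (size_t c = 1; c < counts.size(); ++c)
    if (counts[c] > counts[best]) best = (int)c;
  return best;
}

int build_node(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int lo, int hi, int K, int mtry,
               int min_node) {
  int n = hi - lo;
  std::vector<int> counts(K, 0);
  for (int i = lo; i < hi; ++i) counts[y[idx[i]]]++;
  int node = (int)tree.feat.size();
  tree.feat.push_back(-1); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.pred.push_back(majority(counts));
  double imp = gini_impurity(counts, n);
  if (n < 2 * min_node || imp <= 0.0) return node;

  int p = X.ncol();
  // sample mtry distinct features via partial Fisher-Yates on the R RNG
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j) {
    int pick = j + (int)(unif_rand() * (p - j));
    if (pick >= p) pick = p - 1;
    std::swap(feats[j], feats[pick]);
  }

  double best_score = -1.0; int best_feat = -1; double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int j = 0; j < mtry && j < p; ++j) {
    int f = feats[j];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    std::vector<int> lc(K, 0), rc(counts);
    for (int i = 0; i < n - 1; ++i) {
      int cls = y[ord[i]];
      lc[cls]++; rc[cls]--;
      if (X(ord[i + 1], f) <= X(ord[i], f)) continue;  // no cut between ties
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double score = imp - ((double)nl / n) * gini_impurity(lc, nl)
                         - ((double)nr / n) * gini_impurity(rc, nr);
      if (score > best_score + 1e-12) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
      }
    }
  }
  if (best_feat < 0 || best_score <= 1e-12) return node;

  // partition idx[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tree.feat[node] = best_feat;
  tree.thr[node] = best_thr;
  int l = build_node(tree, X, y, idx, lo, mid, K, mtry, min_node);
  tree.left[node] = l;
  int r = build_node(tree, X, y, idx, mid, hi, K, mtry, min_node);
  tree.right[node] = r;
  return node;
}

int predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feat[node] >= 0)
    node = (X(row, tree.feat[node]) <= tree.thr[node]) ? tree.left[node]
                                                       : tree.right[node];
  return tree.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
IntegerVector rf_fit_predict(NumericMatrix Xtrain, IntegerVector ytrain,
                             NumericMatrix Xtest, int n_classes,
                             int n_trees = 500, int mtry = 0,
                             int min_node = 1) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), nt = Xtest.nrow();
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  IntegerVector y0(n);
  for (int i = 0; i < n; ++i) y0[i] = ytrain[i] - 1;  // to 0-based

  std::vector<std::vector<int> > votes(nt, std::vector<int>(n_classes, 0));
  RNGScope scope;
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    Tree tree;
    build_node(tree, Xtrain, y0, idx, 0, n, n_classes, mtry, min_node);
    for (int i = 0; i < nt; ++i) votes[i][predict_one(tree, Xtest, i)]++;
  }
  IntegerVector out(nt);
  for (int i = 0; i < nt; ++i) out[i] = majority(votes[i]) + 1;  // back to 1-based
  return out;
}
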