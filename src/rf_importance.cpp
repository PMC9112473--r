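#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Random-forest mean-decrease-in-impurity importance for binary outcomes.
// Only the importance vector is needed downstream (shadow-feature selection
// compares real features against permuted copies), so trees are grown but
// never stored and no prediction path exists.
//
// Conventions follow the classical classification forest: bootstrap sample
// of size n per tree, mtry features drawn without replacement at every node,
// Gini impurity, nodes split until pure or below min_node. Randomness comes
// from R's RNG so set.seed() in R governs reproducibility.

static inline double gini_imp(int n1, int n) {
  if (n == 0) return 0.0;
  double p1 = (double)n1 / n;
  return 2.0 * p1 * (1.0 - p1);
}

// draw integer in [0, n) from R's RNG
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct NodeJob { int lo, hi; };

// [[Rcpp::export(name = ".rf_importance_cpp")]]
NumericVector rf_importance_cpp(NumericMatrix X, IntegerVector y,
                                int ntree, int mtry, int min_node) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector importance(p);

  std::vector<int> idx(n);           // bootstrap indices, segment-partitioned
  std::vector<int> feat(p);          // feature pool for mtry sampling
  std::vector<double> vals(n);
  std::vector<int> ord(n), labs(n), tmp(n);
  std::vector<NodeJob> stack;

  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n);
    for (int j = 0; j < p; ++j) feat[j] = j;

    stack.clear();
    stack.push_back({0, n});

    while (!stack.empty()) {
      NodeJob nd = stack.back();
      stack.pop_back();
      const int nn = nd.hi - nd.lo;
      if (nn < 2 || nn < min_node) continue;
      int n1 = 0;
      for (int i = nd.lo; i < nd.hi; ++i) n1 += y[idx[i]];
      if (n1 == 0 || n1 == nn) continue;  // pure node
      const double g_node = gini_imp(n1, nn);

      // sample mtry features without replacement (partial Fisher-Yates)
      int best_f = -1;
      double best_dec = 0.0, best_thr = 0.0;
      for (int m = 0; m < mtry; ++m) {
        int r = m + runif_int(p - m);
        std::swap(feat[m], feat[r]);
        const int f = feat[m];

        for (int i = 0; i < nn; ++i) {
          vals[i] = X(idx[nd.lo + i], f);
          labs[i] = y[idx[nd.lo + i]];
          ord[i] = i;
        }
        std::sort(ord.begin(), ord.begin() + nn,
                  [&](int a, int b) { return vals[a] < vals[b]; });

        int left1 = 0;
        for (int s = 0; s < nn - 1; ++s) {
          left1 += labs[ord[s]];
          if (vals[ord[s]] == vals[ord[s + 1]]) continue;
          const int nl = s + 1, nr = nn - nl;
          double dec = g_node -
            ((double)nl * gini_imp(left1, nl) +
             (double)nr * gini_imp(n1 - left1, nr)) / nn;
          if (dec > best_dec + 1e-15) {
            best_dec = dec;
            best_f = f;
            best_thr = 0.5 * (vals[ord[s]] + vals[ord[s + 1]]);
          }
        }
      }
      if (best_f < 0) continue;  // no valid split among sampled features

      importance[best_f] += best_dec * nn / n;

      // partition the segment on the chosen split
      int k = 0;
      for (int i = nd.lo; i < nd.hi; ++i)
        if (X(idx[i], best_f) <= best_thr) tmp[k++] = idx[i];
      const int n_left = k;
      for (int i = nd.lo; i < nd.hi; ++i)
        if (X(idx[i], best_f) > best_thr) tmp[k++] = idx[i];
      for (int i = 0; i < nn; ++i) idx[nd.lo + i] = tmp[i];

      stack.push_back({nd.lo, nd.lo + n_left});
      stack.push_back({nd.lo + n_left, nd.hi});
    }
  }
  for (int j = 0; j < p; ++j) importance[j] /= ntree;
  return importance;
}
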