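#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal circular-arc two-sample statistic over all boundary pairs
// 0 <= i < j <= n: arc = points i+1..j (1-based), k = j-i,
// T = |mean(arc) - mean(complement)| / sqrt(1/k + 1/(n-k))
// (the noise-scale estimate is a common factor and is applied by the
// caller; it cancels in permutation comparisons).
// Ties are broken by the smallest (i, then j) via strict improvement in
// ascending scan order. Returns -1 in *bi when no feasible pair exists.
static double max_arc(const std::vector<double> &cs, int n, int min_width,
                      int *bi, int *bj) {
  double total = cs[n];
  double best = -1.0;
  int besti = -1, bestj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i;
      if (k < min_width || n - k < min_width) continue;
      double sa = cs[j] - cs[i];
      double diff = sa / k - (total - sa) / (n - k);
      double stat = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (stat > best) {
        best = stat;
        besti = i;
        bestj = j;
      }
    }
  }
  *bi = besti;
  *bj = bestj;
  return best;
}

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
  int bi, bj;
  double stat = max_arc(cs, n, min_width, &bi, &bj);
  if (bi < 0)
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["stat"] = NA_REAL);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = stat);
}

// Permutation test for one candidate split. Uses R's RNG (seed set on the
// R side per node). Early exit once the exceedance count guarantees
// p >= alpha; the split/no-split decision is then identical to running all
// nperm permutations.
// [[Rcpp::export]]
List cbs_split_test(NumericVector x, int min_width, int nperm, double alpha) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
  int bi, bj;
  double obs = max_arc(cs, n, min_width, &bi, &bj);
  if (bi < 0)
    return List::create(_["split"] = false, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["stat"] = NA_REAL,
                        _["p"] = NA_REAL);
  std::vector<double> v(x.begin(), x.end());
  int threshold = (int)std::ceil(alpha * (double)nperm);
  if (threshold < 1) threshold = 1;
  int count = 0, done = 0;
  double cutoff = obs - 1e-9 * (std::fabs(obs) + 1.0);
  for (int p = 0; p < nperm; ++p) {
    for (int t = n - 1; t > 0; --t) {  // Fisher-Yates shuffle
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(v[t], v[u]);
    }
    for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + v[t];
    int pi, pj;
    double s = max_arc(cs, n, min_width, &pi, &pj);
    if (s >= cutoff) ++count;
    ++done;
    if (count >= threshold) break;  // p can no longer fall below alpha
  }
  double pval = (double)count / (double)done;
  bool split = (done == nperm) && (((double)count / (double)nperm) < alpha);
  return List::create(_["split"] = split, _["i"] = bi, _["j"] = bj,
                      _["stat"] = obs, _["p"] = pval);
}
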