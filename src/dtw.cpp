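#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Classic unconstrained DTW between two multichannel series.
// a, b: (time x channel) matrices with equal channel counts.
// Local cost: Euclidean distance across channels; steps {match, insert, delete};
// returns the optimal cumulative cost.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (d != b.ncol()) stop("channel count mismatch");
  if (n == 0 || m == 0) stop("empty series");
  const double inf = std::numeric_limits<double>::infinity();
  // two-row rolling DP table
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (int j = 1; j <= m; ++j) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i - 1, k) - b(j - 1, k);
        c += diff * diff;
      }
      c = std::sqrt(c);
      const double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise DTW distances over a list of (time x channel) matrices.
// [[Rcpp::export(name = ".dtw_pairwise")]]
NumericMatrix dtw_pairwise(List series) {
  const int n = series.size();
  NumericMatrix D(n, n);
  std::vector<NumericMatrix> mats;
  mats.reserve(n);
  for (int i = 0; i < n; ++i) mats.push_back(as<NumericMatrix>(series[i]));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double v = dtw_cost(mats[i], mats[j]);
      D(i, j) = v;
      D(j, i) = v;
    }
  }
  return D;
}
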