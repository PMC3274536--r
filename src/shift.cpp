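#include <Rcpp.h>
using namespace Rcpp;

// Exact permutation distribution of the rank sum of an m-subset of a fixed
// (mid)rank multiset, by the shift algorithm: a dynamic program over items,
// counting k-subsets by their doubled rank sum (midranks are multiples of
// 0.5, so doubling makes every sum integral).  Counts are held as doubles;
// they may exceed 2^53 for larger N, but only their ~1e-15 relative accuracy
// matters for tail probabilities.
//
// ranks2: doubled midranks (positive integers), one per pooled observation.
// m:      subset (gene set) size.
// Returns the vector counts[s] for s = 0..sum(ranks2), where counts[s] is the
// number of m-subsets with doubled rank sum s.
// [[Rcpp::export]]
NumericVector shift_count_subsets(IntegerVector ranks2, int m) {
  const int n = ranks2.size();
  if (m < 0 || m > n) stop("m out of range");
  long total = 0;
  for (int i = 0; i < n; ++i) {
    if (ranks2[i] <= 0) stop("doubled ranks must be positive integers");
    total += ranks2[i];
  }
  const long S = total;
  // dp[k][s], flattened; dp[k*(S+1) + s]
  std::vector<double> dp((size_t)(m + 1) * (S + 1), 0.0);
  dp[0] = 1.0;
  long placed = 0;
  for (int i = 0; i < n; ++i) {
    const int r = ranks2[i];
    placed += r;
    const int kmax = std::min(m, i + 1);
    for (int k = kmax; k >= 1; --k) {
      double* row = &dp[(size_t)k * (S + 1)];
      const double* prev = &dp[(size_t)(k - 1) * (S + 1)];
      const long smax = std::min<long>(placed, S);
      for (long s = smax; s >= r; --s) row[s] += prev[s - r];
    }
  }
  NumericVector out(S + 1);
  const double* last = &dp[(size_t)m * (S + 1)];
  for (long s = 0; s <= S; ++s) out[s] = last[s];
  return out;
}
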