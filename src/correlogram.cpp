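#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive unordered-pair enumeration for the correlogram fingerprint:
// for every pair {p, q} of included pixels, bin the Euclidean distance and
// the intensity sum into a (n_dist_bins x n_sum_bins) count matrix.
// Distances at or beyond max_dist_px overflow into the last distance bin;
// intensity sums live on [0, 510] for 8-bit input.
// [[Rcpp::export]]
IntegerMatrix corr_pair_counts(NumericVector x, NumericVector y,
                               NumericVector inten,
                               int n_dist_bins, int n_sum_bins,
                               double max_dist_px) {
  const int k = x.size();
  IntegerMatrix counts(n_dist_bins, n_sum_bins);
  const double dscale = n_dist_bins / max_dist_px;
  const double sscale = n_sum_bins / 511.0;
  for (int i = 0; i < k - 1; ++i) {
    const double xi = x[i], yi = y[i], Ii = inten[i];
    for (int j = i + 1; j < k; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      const double d = std::sqrt(dx * dx + dy * dy);
      int db = (int)std::floor(d * dscale);
      if (db > n_dist_bins - 1) db = n_dist_bins - 1;
      const double s = Ii + inten[j];
      int sb = (int)std::floor(s * sscale);
      if (sb > n_sum_bins - 1) sb = n_sum_bins - 1;
      if (sb < 0) sb = 0;
      counts(db, sb) += 1;
    }
  }
  return counts;
}
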