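#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in mutual information (bits) between a binned series and its lagged
// copy, for a vector of lags. `bins` are 1-based bin indices in 1..nb.
// Marginals are recomputed per lag over the overlapping stretch, so the
// estimate is the exact plug-in value for each lag. Entropies are assembled
// from integer counts via a log2 lookup table:
//   sum p log2 p = (1/m) * sum c log2 c - log2 m.
// [[Rcpp::export]]
NumericVector ami_curve_cpp(IntegerVector bins, int nb, IntegerVector lags) {
  const int n = bins.size();
  const int L = lags.size();
  const int* b = INTEGER(bins);
  NumericVector out(L);
  std::vector<double> lg(n + 1, 0.0);
  for (int i = 2; i <= n; ++i) lg[i] = std::log2((double)i);
  std::vector<int> joint(nb * nb), pr(nb), pc(nb);
  for (int l = 0; l < L; ++l) {
    const int tau = lags[l];
    const int m = n - tau;
    if (tau < 0 || m < 2) { out[l] = NA_REAL; continue; }
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(pr.begin(), pr.end(), 0);
    std::fill(pc.begin(), pc.end(), 0);
    for (int t = 0; t < m; ++t) {
      const int i = b[t] - 1, j = b[t + tau] - 1;
      ++joint[i + nb * j];
      ++pr[i];
      ++pc[j];
    }
    double sj = 0.0, sr = 0.0, sc = 0.0;
    for (int k = 0; k < nb * nb; ++k) sj += joint[k] * lg[joint[k]];
    for (int k = 0; k < nb; ++k) { sr += pr[k] * lg[pr[k]]; sc += pc[k] * lg[pc[k]]; }
    // MI = H(row) + H(col) - H(joint); the log2(m) terms cancel to one
    out[l] = (sj - sr - sc) / m + lg[m];
  }
  return out;
}

// Mean rescaled range R/S over non-overlapping blocks of each window size.
// Returns one value per window size (NA when no block has positive sd);
// the Hurst slope regression stays in R.
// [[Rcpp::export]]
NumericVector rs_means_cpp(NumericVector x, IntegerVector sizes) {
  const int n = x.size();
  const double* v = REAL(x);
  NumericVector out(sizes.size());
  for (int s = 0; s < sizes.size(); ++s) {
    const int m = sizes[s];
    const int nb = n / m;
    double acc = 0.0;
    int cnt = 0;
    for (int blk = 0; blk < nb; ++blk) {
      const double* y = v + blk * m;
      double mean = 0.0;
      for (int i = 0; i < m; ++i) mean += y[i];
      mean /= m;
      double cs = 0.0, cmin = 0.0, cmax = 0.0, ss = 0.0;
      for (int i = 0; i < m; ++i) {
        const double d = y[i] - mean;
        ss += d * d;
        cs += d;
        if (cs < cmin) cmin = cs;
        if (cs > cmax) cmax = cs;
      }
      const double sd = std::sqrt(ss / (m - 1));
      if (sd > 0) { acc += (cmax - cmin) / sd; ++cnt; }
    }
    out[s] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}
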