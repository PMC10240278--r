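#include <Rcpp.h>
using namespace Rcpp;

// Greedy single-pass binning of peak centroids scanned in ascending m/z.
// A peak joins the current bin while it lies within tol_ppm of the bin's
// running intensity-weighted mean; otherwise it opens a new bin.
// mz must be sorted ascending; returns 1-based bin ids.
// [[Rcpp::export(name = ".bin_scan")]]
IntegerVector bin_scan(NumericVector mz, NumericVector intensity, double tol_ppm) {
  const R_xlen_t n = mz.size();
  IntegerVector bin(n);
  if (n == 0) return bin;
  int cur = 1;
  double wsum = intensity[0] > 0 ? intensity[0] : 1e-12;
  double mean = mz[0];
  bin[0] = cur;
  for (R_xlen_t i = 1; i < n; ++i) {
    const double dev = (mz[i] - mean) / mean * 1e6;
    if (dev <= tol_ppm) {
      const double w = intensity[i] > 0 ? intensity[i] : 1e-12;
      mean = (mean * wsum + mz[i] * w) / (wsum + w);
      wsum += w;
    } else {
      ++cur;
      mean = mz[i];
      wsum = intensity[i] > 0 ? intensity[i] : 1e-12;
    }
    bin[i] = cur;
  }
  return bin;
}
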