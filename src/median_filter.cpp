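#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median filter over the cubic neighborhood of half-width `radius`, computed
// only at voxels where mask != 0 and drawing only on masked neighbors.
// Voxels outside the mask are returned as 0.
// [[Rcpp::export(name = ".masked_median_filter")]]
NumericVector masked_median_filter(NumericVector x, IntegerVector mask,
                                   IntegerVector dims, int radius) {
  if (radius < 1) stop("radius must be >= 1");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n || mask.size() != n) stop("dims do not match array length");
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int k = 0; k < nz; ++k) {
    const int k0 = std::max(0, k - radius), k1 = std::min(nz - 1, k + radius);
    for (int j = 0; j < ny; ++j) {
      const int j0 = std::max(0, j - radius), j1 = std::min(ny - 1, j + radius);
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) { out[idx] = 0.0; continue; }
        const int i0 = std::max(0, i - radius), i1 = std::min(nx - 1, i + radius);
        buf.clear();
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj) {
            const R_xlen_t base = (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            for (int ii = i0; ii <= i1; ++ii) {
              const R_xlen_t nidx = ii + base;
              if (mask[nidx]) buf.push_back(x[nidx]);
            }
          }
        const size_t m = buf.size();
        std::vector<double>::iterator mid = buf.begin() + m / 2;
        std::nth_element(buf.begin(), mid, buf.end());
        if (m % 2 == 1) {
          out[idx] = *mid;
        } else {
          double hi = *mid;
          double lo = *std::max_element(buf.begin(), mid);
          out[idx] = 0.5 * (lo + hi);
        }
      }
    }
  }
  return out;
}
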