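#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Slice-wise local entropy: for every voxel, the Shannon entropy (bits) of
// the nb-bin histogram of the in-plane square window of half-width r
// centred on it, clipped at the slice borders. `bin` holds 1-based bin
// indices; `eps` is the stabiliser inside the logarithm.
// [[Rcpp::export]]
NumericVector cpp_entropy_map(IntegerVector bin, IntegerVector dims,
                              int nb, int r, double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nx * ny * nz);
  std::vector<int> counts(nb);
  const double inv_log2 = 1.0 / std::log(2.0);
  for (int z = 0; z < nz; ++z) {
    const int *slice = bin.begin() + (R_xlen_t) z * nx * ny;
    double *oslice = out.begin() + (R_xlen_t) z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      const int ylo = y - r < 0 ? 0 : y - r;
      const int yhi = y + r >= ny ? ny - 1 : y + r;
      for (int x = 0; x < nx; ++x) {
        const int xlo = x - r < 0 ? 0 : x - r;
        const int xhi = x + r >= nx ? nx - 1 : x + r;
        std::fill(counts.begin(), counts.end(), 0);
        int w = 0;
        for (int yy = ylo; yy <= yhi; ++yy)
          for (int xx = xlo; xx <= xhi; ++xx) {
            ++counts[slice[xx + nx * yy] - 1];
            ++w;
          }
        double h = 0.0;
        for (int b = 0; b < nb; ++b) {
          if (!counts[b]) continue;
          const double p = (double) counts[b] / w;
          h -= p * std::log(p + eps) * inv_log2;
        }
        oslice[x + nx * y] = h > 0.0 ? h : 0.0;
      }
    }
  }
  return out;
}
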