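#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable 1D convolution of a 3D array along `axis` (0-based) with an
// odd-length centred kernel. Edges are renormalised over the in-bounds taps
// when `renorm` is true (smoothing kernels), zero-padded otherwise.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector arr, IntegerVector dims,
                                NumericVector kernel, int axis, bool renorm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  const int half = (klen - 1) / 2;
  NumericVector out(arr.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int na = n[axis];
  const int sa = stride[axis];
  // iterate over all lines along `axis`
  const int o1 = axis == 0 ? 1 : 0;
  const int o2 = axis == 2 ? 1 : 2;
  for (int j2 = 0; j2 < n[o2]; ++j2) {
    for (int j1 = 0; j1 < n[o1]; ++j1) {
      const R_xlen_t base = (R_xlen_t) j1 * stride[o1] +
        (R_xlen_t) j2 * stride[o2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0, wsum = 0.0;
        for (int t = 0; t < klen; ++t) {
          const int src = i + t - half;
          if (src < 0 || src >= na) continue;
          acc += kernel[t] * arr[base + (R_xlen_t) src * sa];
          wsum += kernel[t];
        }
        out[base + (R_xlen_t) i * sa] =
          renorm ? (wsum > 1e-12 ? acc / wsum : 0.0) : acc;
      }
    }
  }
  return out;
}
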