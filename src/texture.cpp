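#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gray-level texture matrix construction. All functions take a discretised
// volume `g` (integer vector with dim attribute applied on the R side,
// passed here together with dims): g == 0 marks voxels outside the region,
// 1..Ng are gray levels. Geometry is the voxel lattice; distance 1.

// The 13 unique 3D direction vectors (one of each +/- pair).
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int vox(const IntegerVector &g, int x, int y, int z,
                      int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return -1;
  return g[x + nx * (y + ny * z)];
}

// Co-occurrence counts, symmetric, one Ng x Ng slab per direction.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector g, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *slab = out.begin() + d * ng * ng;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int gi = g[x + nx * (y + ny * z)];
          if (gi <= 0) continue;
          const int gj = vox(g, x + dx, y + dy, z + dz, nx, ny, nz);
          if (gj <= 0) continue;
          slab[(gi - 1) + ng * (gj - 1)] += 1.0;
          slab[(gj - 1) + ng * (gi - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts, one Ng x maxlen slab per direction.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector g, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = nx > ny ? nx : ny;
  if (nz > maxlen) maxlen = nz;
  NumericVector out(ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *slab = out.begin() + d * ng * maxlen;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int gi = g[x + nx * (y + ny * z)];
          if (gi <= 0) continue;
          // run start: predecessor along -d is absent or different
          if (vox(g, x - dx, y - dy, z - dz, nx, ny, nz) == gi) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (vox(g, cx, cy, cz, nx, ny, nz) == gi) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxlen) len = maxlen;
          slab[(gi - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Size-zone decomposition: 26-connected components of equal gray level.
// Returns the gray level and size of every zone.
// [[Rcpp::export]]
List cpp_glszm_zones(IntegerVector g, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zg, zs, stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || g[start] <= 0) continue;
    const int lev = g[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int ax = x + dx, ay = y + dy, az = z + dz;
            if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
              continue;
            const int w = ax + nx * (ay + ny * az);
            if (!seen[w] && g[w] == lev) { seen[w] = 1; stack.push_back(w); }
          }
    }
    zg.push_back(lev);
    zs.push_back(size);
  }
  return List::create(_["gray"] = wrap(zg), _["size"] = wrap(zs));
}

// Dependence counts: for each voxel, number of 26-neighbours (inside the
// region) within `alpha` gray levels. Ng x 27 count matrix (dependence 0..26).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector g, IntegerVector dims, int ng, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int gi = g[x + nx * (y + ny * z)];
        if (gi <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int gj = vox(g, x + dx, y + dy, z + dz, nx, ny, nz);
              if (gj > 0 && std::abs(gj - gi) <= alpha) ++dep;
            }
        out(gi - 1, dep) += 1.0;
      }
  return out;
}

// Neighbouring gray-tone difference: per gray level, the count n_i of voxels
// with at least one in-region neighbour and the summed absolute difference
// s_i between the level and the mean of its in-region 26-neighbourhood.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector g, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector s(ng), n(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int gi = g[x + nx * (y + ny * z)];
        if (gi <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int gj = vox(g, x + dx, y + dy, z + dz, nx, ny, nz);
              if (gj > 0) { sum += gj; ++cnt; }
            }
        if (cnt > 0) {
          s[gi - 1] += std::fabs(gi - sum / cnt);
          n[gi - 1] += 1.0;
        }
      }
  return List::create(_["s"] = s, _["n"] = n);
}
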