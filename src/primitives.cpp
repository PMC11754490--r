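#include <Rcpp.h>
#include <vector>
#include <cfloat>
using namespace Rcpp;

// 3D image primitives shared by the morphology, segmentation and calcium
// cascade code. Arrays arrive as flat vectors in R's column-major layout
// with dims (nx, ny, nz); axis 3 indexes axial slices.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected-component labelling by iterative flood fill. `offsets` is the
// full neighbourhood (one row per neighbour, columns dx,dy,dz). Labels are
// assigned in scan order, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  const int noff = offsets.nrow();
  std::vector<int> dx(noff), dy(noff), dz(noff);
  for (int k = 0; k < noff; ++k) {
    dx[k] = offsets(k, 0); dy[k] = offsets(k, 1); dz[k] = offsets(k, 2);
  }
  std::vector<int> stack;
  int next_label = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (!mask[i] || labels[i]) continue;
        ++next_label;
        labels[i] = next_label;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          const int cur = stack.back();
          stack.pop_back();
          const int cz = cur / (nx * ny);
          const int rem = cur - cz * nx * ny;
          const int cy = rem / nx;
          const int cx = rem - cy * nx;
          for (int k = 0; k < noff; ++k) {
            const int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            const int j = idx3(px, py, pz, nx, ny);
            if (mask[j] && !labels[j]) {
              labels[j] = next_label;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  return labels;
}

// One-dimensional squared-distance transform (lower envelope of parabolas)
// with physical sample spacing s, applied in place over a strided line.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -DBL_MAX;
  z[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    const double sq = f[q] + xq * xq;
    double ss;
    for (;;) {
      const double xv = v[k] * s;
      ss = (sq - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (ss <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = ss;
    z[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance (mm^2) from every voxel to
// the nearest set voxel (Felzenszwalb & Huttenlocher, separable passes).
// Voxels of an empty mask get a large finite sentinel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  const double BIG = 1e20;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      const int base = idx3(0, y, zz, nx, ny);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, out, v, z, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx3(x, y, zz, nx, ny)];
      dt1d(f, out, v, z, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[idx3(x, y, zz, nx, ny)] = out[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int zz = 0; zz < nz; ++zz) f[zz] = d[idx3(x, y, zz, nx, ny)];
      dt1d(f, out, v, z, nz, spacing[2]);
      for (int zz = 0; zz < nz; ++zz) d[idx3(x, y, zz, nx, ny)] = out[zz];
    }
  return d;
}

// Binary dilation/erosion by an explicit structuring element given as
// offsets. Outside the array is treated as background, so erosion shrinks
// at the borders and dilation never writes out of bounds.
// [[Rcpp::export]]
LogicalVector cpp_morph_offsets(LogicalVector mask, IntegerVector dims,
                                IntegerMatrix offsets, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  LogicalVector out(n, false);
  const int noff = offsets.nrow();
  std::vector<int> dx(noff), dy(noff), dz(noff);
  for (int k = 0; k < noff; ++k) {
    dx[k] = offsets(k, 0); dy[k] = offsets(k, 1); dz[k] = offsets(k, 2);
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i = idx3(x, y, z, nx, ny);
        if (dilate) {
          if (!mask[i]) continue;
          for (int k = 0; k < noff; ++k) {
            const int px = x + dx[k], py = y + dy[k], pz = z + dz[k];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            out[idx3(px, py, pz, nx, ny)] = true;
          }
        } else {
          if (!mask[i]) continue;
          bool keep = true;
          for (int k = 0; k < noff; ++k) {
            const int px = x + dx[k], py = y + dy[k], pz = z + dz[k];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 ||
                pz >= nz || !mask[idx3(px, py, pz, nx, ny)]) {
              keep = false;
              break;
            }
          }
          if (keep) out[i] = true;
        }
      }
  return out;
}
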