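// Hot lattice kernels: explicit finite-volume diffusion step and Moore-
// neighborhood occupancy counts on the 3-D voxel grid. Both are called
// every simulation step; the R front ends validate arguments.
#include <Rcpp.h>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// One explicit FVM update of dC/dt = D lap(C) - decay C + sources with
// no-flux boundaries: an out-of-domain neighbor is replaced by the cell
// itself so its face carries zero flux and mass is conserved exactly.
// [[Rcpp::export]]
NumericVector diffuse_step_cpp(NumericVector field, IntegerVector dims,
                               double D, double decay,
                               Nullable<NumericVector> sources,
                               double dt, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double r = D / (h * h);
  NumericVector out(field.size());
  const double *f = field.begin();
  double *o = out.begin();
  const double *src = nullptr;
  if (sources.isNotNull()) {
    NumericVector s(sources);
    src = s.begin();
    // s is a view on the SEXP passed in; keep using the raw pointer only
    // within this call
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx = lin(i, j, k, nx, ny);
          double c = f[idx];
          double nb = (i > 0      ? f[idx - 1]       : c)
                    + (i < nx - 1 ? f[idx + 1]       : c)
                    + (j > 0      ? f[idx - nx]      : c)
                    + (j < ny - 1 ? f[idx + nx]      : c)
                    + (k > 0      ? f[idx - nx * ny] : c)
                    + (k < nz - 1 ? f[idx + nx * ny] : c);
          o[idx] = c + dt * (r * (nb - 6.0 * c) - decay * c + src[idx]);
        }
    return out;
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx = lin(i, j, k, nx, ny);
        double c = f[idx];
        double nb = (i > 0      ? f[idx - 1]       : c)
                  + (i < nx - 1 ? f[idx + 1]       : c)
                  + (j > 0      ? f[idx - nx]      : c)
                  + (j < ny - 1 ? f[idx + nx]      : c)
                  + (k > 0      ? f[idx - nx * ny] : c)
                  + (k < nz - 1 ? f[idx + nx * ny] : c);
        o[idx] = c + dt * (r * (nb - 6.0 * c) - decay * c);
      }
  return out;
}

// Number of occupied voxels in the 26-voxel Moore neighborhood of every
// voxel (the voxel itself excluded), via three separable box-sum passes.
// [[Rcpp::export]]
IntegerVector moore_count_cpp(IntegerVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = occ.size();
  std::vector<int> a(occ.begin(), occ.end()), b(n);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx = lin(i, j, k, nx, ny);
        int s = a[idx];
        if (i > 0) s += a[idx - 1];
        if (i < nx - 1) s += a[idx + 1];
        b[idx] = s;
      }
  std::swap(a, b);
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx = lin(i, j, k, nx, ny);
        int s = a[idx];
        if (j > 0) s += a[idx - nx];
        if (j < ny - 1) s += a[idx + nx];
        b[idx] = s;
      }
  std::swap(a, b);
  // z pass, subtracting the center occupancy
  IntegerVector res(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx = lin(i, j, k, nx, ny);
        int s = a[idx];
        if (k > 0) s += a[idx - nx * ny];
        if (k < nz - 1) s += a[idx + nx * ny];
        res[idx] = s - occ[idx];
      }
  return res;
}
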