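#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact anisotropic squared Euclidean distance transform, computed as three
// separable 1-D lower-envelope passes (Felzenszwalb & Huttenlocher). Each 1-D
// pass works on physical coordinates i * w, so anisotropic voxel spacing is
// handled exactly rather than by index arithmetic.

static const double BIG = 1e15;   // stands in for +inf in parabola heights
static const double ZBIG = 1e30;  // sentinel for envelope breakpoints

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  if (n == 1) { d[0] = f[0]; return; }
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -ZBIG;
  z[1] = ZBIG;
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      int p = v[k];
      // abscissae are physical positions q*w, so the intersection of the
      // parabolas at p*w and q*w divides by 2*(q*w - p*w)
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
          (2.0 * w * (q - p));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZBIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * w;
    while (z[k + 1] < x) k++;
    int p = v[k];
    d[q] = (x - p * w) * (x - p * w) + f[p];
  }
}

// mask: logical volume in R's column-major layout; dim: (nx, ny, nz);
// spacing: voxel size in mm per axis. Returns distances in mm.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (mask.size() != ntot)
    stop("mask length does not match dim");

  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; i++)
    g[i] = (mask[i] == TRUE) ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) g[base + i] = d[i];
    }

  // pass along y (stride nx)
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; j++) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; j++) g[base + (R_xlen_t)j * nx] = d[j];
    }

  // pass along z (stride nx*ny)
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int k = 0; k < nz; k++) f[k] = g[base + (R_xlen_t)k * sxy];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; k++) g[base + (R_xlen_t)k * sxy] = d[k];
    }

  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = std::sqrt(g[i]);
  return out;
}

// Exact segment/mask intersection by Amanatides-Woo voxel traversal: does the
// segment P0[s,] -> P1[s,] pass through any TRUE voxel (voxel i occupies the
// box of half-voxel extent around its center)? Unlike point sampling this
// verdict cannot change under refinement, so it backs the collision hard
// constraint. Endpoints are expected inside the grid (the planner guarantees
// it); out-of-grid cells are simply skipped.
// [[Rcpp::export(name = ".seg_hits_cpp")]]
LogicalVector seg_hits_cpp(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix P0, NumericMatrix P1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nseg = P0.nrow();
  LogicalVector out(nseg);
  for (int s = 0; s < nseg; s++) {
    double s0[3], d[3];
    int i[3], iend[3], stp[3];
    double tmax[3], tdel[3];
    for (int a = 0; a < 3; a++) {
      s0[a] = (P0(s, a) - origin[a]) / spacing[a] + 0.5;
      double s1 = (P1(s, a) - origin[a]) / spacing[a] + 0.5;
      d[a] = s1 - s0[a];
      i[a] = (int)std::floor(s0[a]);
      iend[a] = (int)std::floor(s1);
      if (d[a] > 0) {
        stp[a] = 1; tmax[a] = ((i[a] + 1) - s0[a]) / d[a]; tdel[a] = 1.0 / d[a];
      } else if (d[a] < 0) {
        stp[a] = -1; tmax[a] = (i[a] - s0[a]) / d[a]; tdel[a] = -1.0 / d[a];
      } else {
        stp[a] = 0; tmax[a] = R_PosInf; tdel[a] = R_PosInf;
      }
    }
    bool hit = false;
    const int guard = 2 * (nx + ny + nz) + 8;
    for (int it = 0; it < guard; it++) {
      if (i[0] >= 0 && i[0] < nx && i[1] >= 0 && i[1] < ny &&
          i[2] >= 0 && i[2] < nz) {
        R_xlen_t lin = i[0] + (R_xlen_t)nx * (i[1] + (R_xlen_t)ny * i[2]);
        if (mask[lin]) { hit = true; break; }
      }
      if (i[0] == iend[0] && i[1] == iend[1] && i[2] == iend[2]) break;
      int a = 0;
      if (tmax[1] < tmax[a]) a = 1;
      if (tmax[2] < tmax[a]) a = 2;
      if (tmax[a] > 1.0) break;
      i[a] += stp[a];
      tmax[a] += tdel[a];
    }
    out[s] = hit;
  }
  return out;
}
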