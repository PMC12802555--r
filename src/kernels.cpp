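#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---- exact 1D squared distance transform (Felzenszwalb & Huttenlocher) ----
// f: squared distances sampled on a line with sample spacing `s`.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sq = f[q] + s2 * q * q;
    double inter;
    while (true) {
      int p = v[k];
      inter = (sq - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (inter <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
  f = d;
}

// Exact anisotropic Euclidean distance transform of a 3D logical array.
// Distances (mm) from every voxel centre to the nearest TRUE voxel centre.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: keeps the envelope intersections finite on lines
  // with no feature voxel (infinity would turn them into NaN)
  const double INF = 1e15;
  NumericVector out(nx * (R_xlen_t)ny * nz);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // axis x
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = line[i];
    }
  // axis y
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) line[j] = out[base + (R_xlen_t)nx * j];
      dt1d(line, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = line[j];
    }
  // axis z
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) line[k] = out[base + stride * k];
      dt1d(line, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + stride * k] = line[k];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = std::sqrt(out[i]);
  return out;
}

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// pts: N x 3 matrix of (i, j, k) index coordinates. Out-of-grid reads `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
    int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = (nx == 1) ? i0 : i0 + 1;
    int j1 = (ny == 1) ? j0 : j0 + 1;
    int k1 = (nz == 1) ? k0 : k0 + 1;
    R_xlen_t sxy = (R_xlen_t)nx * ny;
    double c000 = vol[i0 + (R_xlen_t)nx * j0 + sxy * k0];
    double c100 = vol[i1 + (R_xlen_t)nx * j0 + sxy * k0];
    double c010 = vol[i0 + (R_xlen_t)nx * j1 + sxy * k0];
    double c110 = vol[i1 + (R_xlen_t)nx * j1 + sxy * k0];
    double c001 = vol[i0 + (R_xlen_t)nx * j0 + sxy * k1];
    double c101 = vol[i1 + (R_xlen_t)nx * j0 + sxy * k1];
    double c011 = vol[i0 + (R_xlen_t)nx * j1 + sxy * k1];
    double c111 = vol[i1 + (R_xlen_t)nx * j1 + sxy * k1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable Gaussian smoothing, replicate boundary, kernel truncated at 3 sigma.
// sigma given in voxels per axis; sigma <= 0 skips that axis. Lines are
// copied into a padded local buffer so the inner loop is contiguous.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(vol);
  const int n_ax[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (double& kv : ker) kv /= sum;
    const int len = n_ax[ax];
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? nx : (R_xlen_t)nx * ny;
    std::vector<double> buf(len + 2 * r);
    int na = (ax == 0) ? ny : nx;
    int nb = (ax == 2) ? ny : nz;
    double* pc = REAL(cur);
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        R_xlen_t base;
        if (ax == 0)      base = (R_xlen_t)nx * a + (R_xlen_t)nx * ny * b;
        else if (ax == 1) base = a + (R_xlen_t)nx * ny * b;
        else              base = a + (R_xlen_t)nx * b;
        for (int q = 0; q < len; ++q) buf[r + q] = pc[base + stride * q];
        for (int t = 0; t < r; ++t) {
          buf[t] = buf[r];
          buf[r + len + t] = buf[r + len - 1];
        }
        for (int q = 0; q < len; ++q) {
          double acc = 0.0;
          const double* bp = &buf[q];
          for (int t = 0; t <= 2 * r; ++t) acc += ker[t] * bp[t];
          pc[base + stride * q] = acc;
        }
      }
  }
  return cur;
}

// Trilinear sampling of several arrays (same lattice) at shared points.
// Returns an N x k matrix; out-of-grid points read fill.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_multi(List vols, IntegerVector dim,
                                  NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int k = vols.size();
  const R_xlen_t n = pts.nrow();
  std::vector<const double*> vp(k);
  for (int v = 0; v < k; ++v) {
    NumericVector nv = vols[v];
    vp[v] = REAL(nv);
  }
  NumericMatrix out(n, k);
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      for (int v = 0; v < k; ++v) out(p, v) = fill;
      continue;
    }
    int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
    int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = (nx == 1) ? i0 : i0 + 1;
    int j1 = (ny == 1) ? j0 : j0 + 1;
    int k1 = (nz == 1) ? k0 : k0 + 1;
    R_xlen_t o000 = i0 + (R_xlen_t)nx * j0 + sxy * k0;
    R_xlen_t o100 = i1 + (R_xlen_t)nx * j0 + sxy * k0;
    R_xlen_t o010 = i0 + (R_xlen_t)nx * j1 + sxy * k0;
    R_xlen_t o110 = i1 + (R_xlen_t)nx * j1 + sxy * k0;
    R_xlen_t o001 = i0 + (R_xlen_t)nx * j0 + sxy * k1;
    R_xlen_t o101 = i1 + (R_xlen_t)nx * j0 + sxy * k1;
    R_xlen_t o011 = i0 + (R_xlen_t)nx * j1 + sxy * k1;
    R_xlen_t o111 = i1 + (R_xlen_t)nx * j1 + sxy * k1;
    double w000 = (1 - fx) * (1 - fy) * (1 - fz);
    double w100 = fx * (1 - fy) * (1 - fz);
    double w010 = (1 - fx) * fy * (1 - fz);
    double w110 = fx * fy * (1 - fz);
    double w001 = (1 - fx) * (1 - fy) * fz;
    double w101 = fx * (1 - fy) * fz;
    double w011 = (1 - fx) * fy * fz;
    double w111 = fx * fy * fz;
    for (int v = 0; v < k; ++v) {
      const double* a = vp[v];
      out(p, v) = w000 * a[o000] + w100 * a[o100] + w010 * a[o010] +
                  w110 * a[o110] + w001 * a[o001] + w101 * a[o101] +
                  w011 * a[o011] + w111 * a[o111];
    }
  }
  return out;
}

// Squared-gradient (strain) energy of a 3-component displacement field and
// its gradient. Forward differences; E = sum(diff^2) (caller normalises).
// [[Rcpp::export]]
List cpp_strain(NumericVector u, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector G(u.size());
  double E = 0.0;
  const double* pu = REAL(u);
  double* pg = REAL(G);
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int lens[3] = {nx, ny, nz};
  for (int c = 0; c < 3; ++c) {
    const double* uc = pu + c * nvox;
    double* gc = pg + c * nvox;
    for (int ax = 0; ax < 3; ++ax) {
      if (lens[ax] < 2) continue;
      const double inv_h = 1.0 / spacing[ax];
      const R_xlen_t st = strides[ax];
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          R_xlen_t row = (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k;
          for (int i = 0; i < nx; ++i) {
            // forward difference along ax if not at the upper boundary
            bool ok = (ax == 0) ? (i < nx - 1) : (ax == 1) ? (j < ny - 1)
                                                           : (k < nz - 1);
            if (!ok) continue;
            R_xlen_t q = row + i;
            double df = (uc[q + st] - uc[q]) * inv_h;
            E += df * df;
            gc[q + st] += 2.0 * df * inv_h;
            gc[q] -= 2.0 * df * inv_h;
          }
        }
    }
  }
  return List::create(_["E"] = E, _["G"] = G);
}
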