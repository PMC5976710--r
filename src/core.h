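#ifndef ABLAFUSE_CORE_H
#define ABLAFUSE_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Shared kernels: index<->world maps, interpolation (nearest / trilinear /
// prefiltered cubic B-spline) and transform-chain evaluation. All voxel
// indices are 0-based; a chain maps fixed-space world mm to moving-space
// world mm, stages applied in list order.

struct Affine34 {
  double m[12]; // row-major 3x4
  inline void apply(const double in[3], double out[3]) const {
    for (int r = 0; r < 3; ++r)
      out[r] = m[4*r] * in[0] + m[4*r+1] * in[1] + m[4*r+2] * in[2] + m[4*r+3];
  }
};

inline Affine34 affine_from_matrix(const Rcpp::NumericMatrix& M) {
  Affine34 a;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) a.m[4*r + c] = M(r, c);
  return a;
}

// cubic B-spline kernel, support |s| < 2
inline double bspline3_kernel(double s) {
  s = std::fabs(s);
  if (s < 1.0) return (4.0 - 6.0 * s * s + 3.0 * s * s * s) / 6.0;
  if (s < 2.0) { double t = 2.0 - s; return t * t * t / 6.0; }
  return 0.0;
}

struct BsplineFFD {
  double origin[3], spacing[3];
  int dims[3];
  const double* coef; // [dims, 3] column-major R array
  inline void displacement(const double x[3], double d[3]) const {
    double u[3]; int i0[3];
    for (int a = 0; a < 3; ++a) {
      u[a] = (x[a] - origin[a]) / spacing[a];
      i0[a] = (int)std::floor(u[a]);
    }
    d[0] = d[1] = d[2] = 0.0;
    const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2], nxyz = nx*ny*nz;
    double wx[4], wy[4], wz[4];
    int jx[4], jy[4], jz[4];
    for (int k = 0; k < 4; ++k) {
      int j;
      j = i0[0] - 1 + k; wx[k] = bspline3_kernel(u[0] - j);
      jx[k] = j < 0 ? 0 : (j >= nx ? (int)nx - 1 : j);
      j = i0[1] - 1 + k; wy[k] = bspline3_kernel(u[1] - j);
      jy[k] = j < 0 ? 0 : (j >= ny ? (int)ny - 1 : j);
      j = i0[2] - 1 + k; wz[k] = bspline3_kernel(u[2] - j);
      jz[k] = j < 0 ? 0 : (j >= nz ? (int)nz - 1 : j);
    }
    for (int kz = 0; kz < 4; ++kz) {
      if (wz[kz] == 0.0) continue;
      for (int ky = 0; ky < 4; ++ky) {
        double wyz = wy[ky] * wz[kz];
        if (wyz == 0.0) continue;
        R_xlen_t base = (R_xlen_t)jz[kz] * nx * ny + (R_xlen_t)jy[ky] * nx;
        for (int kx = 0; kx < 4; ++kx) {
          double w = wx[kx] * wyz;
          if (w == 0.0) continue;
          R_xlen_t idx = base + jx[kx];
          d[0] += w * coef[idx];
          d[1] += w * coef[idx + nxyz];
          d[2] += w * coef[idx + 2 * nxyz];
        }
      }
    }
  }
};

struct Stage {
  int type; // 0 affine, 1 bspline
  Affine34 A;
  BsplineFFD B;
};

struct Chain {
  std::vector<Stage> stages;
  inline void apply(const double in[3], double out[3]) const {
    double p[3] = {in[0], in[1], in[2]};
    double q[3];
    for (size_t s = 0; s < stages.size(); ++s) {
      if (stages[s].type == 0) {
        stages[s].A.apply(p, q);
        p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
      } else {
        double d[3];
        stages[s].B.displacement(p, d);
        p[0] += d[0]; p[1] += d[1]; p[2] += d[2];
      }
    }
    out[0] = p[0]; out[1] = p[1]; out[2] = p[2];
  }
};

inline Chain parse_chain(const Rcpp::List& spec) {
  Chain ch;
  for (R_xlen_t i = 0; i < spec.size(); ++i) {
    Rcpp::List el = spec[i];
    Stage st;
    st.type = Rcpp::as<int>(el["type"]);
    if (st.type == 0) {
      st.A = affine_from_matrix(Rcpp::as<Rcpp::NumericMatrix>(el["M"]));
    } else {
      Rcpp::NumericVector o = el["origin"], s = el["spacing"];
      Rcpp::IntegerVector d = el["dims"];
      Rcpp::NumericVector cf = el["coef"];
      for (int a = 0; a < 3; ++a) {
        st.B.origin[a] = o[a]; st.B.spacing[a] = s[a]; st.B.dims[a] = d[a];
      }
      st.B.coef = REAL(cf);
    }
    ch.stages.push_back(st);
  }
  return ch;
}

// ---- interpolation on a 3D array (continuous 0-based index space) ----

struct Grid3 {
  const double* v;
  R_xlen_t nx, ny, nz;
  inline double at(R_xlen_t i, R_xlen_t j, R_xlen_t k) const {
    return v[i + nx * (j + ny * k)];
  }
  inline bool inside(const double x[3]) const {
    return x[0] >= 0.0 && x[0] <= nx - 1.0 &&
           x[1] >= 0.0 && x[1] <= ny - 1.0 &&
           x[2] >= 0.0 && x[2] <= nz - 1.0;
  }
  inline double nearest(const double x[3]) const {
    R_xlen_t i = (R_xlen_t)std::floor(x[0] + 0.5);
    R_xlen_t j = (R_xlen_t)std::floor(x[1] + 0.5);
    R_xlen_t k = (R_xlen_t)std::floor(x[2] + 0.5);
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    return at(i, j, k);
  }
  inline double trilinear(const double x[3]) const {
    R_xlen_t i = (R_xlen_t)std::floor(x[0]);
    R_xlen_t j = (R_xlen_t)std::floor(x[1]);
    R_xlen_t k = (R_xlen_t)std::floor(x[2]);
    if (i >= nx - 1) i = nx - 2; if (i < 0) i = 0;
    if (j >= ny - 1) j = ny - 2; if (j < 0) j = 0;
    if (k >= nz - 1) k = nz - 2; if (k < 0) k = 0;
    double fx = x[0] - i, fy = x[1] - j, fz = x[2] - k;
    double c00 = at(i, j, k)     * (1 - fx) + at(i + 1, j, k)     * fx;
    double c10 = at(i, j + 1, k) * (1 - fx) + at(i + 1, j + 1, k) * fx;
    double c01 = at(i, j, k + 1)     * (1 - fx) + at(i + 1, j, k + 1)     * fx;
    double c11 = at(i, j + 1, k + 1) * (1 - fx) + at(i + 1, j + 1, k + 1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
  // cubic B-spline evaluation of a *coefficient* grid (mirror boundary)
  inline double cubic(const double x[3]) const {
    int i0[3]; double u[3];
    u[0] = x[0]; u[1] = x[1]; u[2] = x[2];
    for (int a = 0; a < 3; ++a) i0[a] = (int)std::floor(u[a]);
    const R_xlen_t n[3] = {nx, ny, nz};
    double w[3][4]; R_xlen_t idx[3][4];
    for (int a = 0; a < 3; ++a)
      for (int k = 0; k < 4; ++k) {
        long j = (long)i0[a] - 1 + k;
        w[a][k] = bspline3_kernel(u[a] - (double)j);
        // mirror-on-bounds index (period 2n-2)
        long m = n[a] > 1 ? 2 * ((long)n[a] - 1) : 1;
        j = ((j % m) + m) % m;
        if (j >= (long)n[a]) j = m - j;
        idx[a][k] = (R_xlen_t)j;
      }
    double acc = 0.0;
    for (int kz = 0; kz < 4; ++kz) {
      if (w[2][kz] == 0.0) continue;
      for (int ky = 0; ky < 4; ++ky) {
        double wyz = w[1][ky] * w[2][kz];
        if (wyz == 0.0) continue;
        R_xlen_t base = nx * (idx[1][ky] + ny * idx[2][kz]);
        for (int kx = 0; kx < 4; ++kx)
          if (w[0][kx] != 0.0) acc += w[0][kx] * wyz * v[base + idx[0][kx]];
      }
    }
    return acc;
  }
};

// In-place cubic B-spline prefilter (Unser), mirror boundary, so that
// Grid3::cubic interpolates the original samples exactly.
inline void bspline3_prefilter_axis(double* data, R_xlen_t n, R_xlen_t stride,
                                    R_xlen_t nlines, R_xlen_t line_stride,
                                    R_xlen_t nplanes, R_xlen_t plane_stride) {
  const double z = -0.26794919243112270647; // sqrt(3) - 2
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
  if (horizon > n) horizon = (int)n;
  std::vector<double> c(n);
  for (R_xlen_t p = 0; p < nplanes; ++p)
    for (R_xlen_t l = 0; l < nlines; ++l) {
      double* s = data + p * plane_stride + l * line_stride;
      for (R_xlen_t i = 0; i < n; ++i) c[i] = s[i * stride] * lambda;
      // causal init over the mirrored extension: truncated sum when the
      // signal is long enough, exact closed form otherwise
      double sum;
      if (horizon < n) {
        sum = c[0];
        double zk = z;
        for (int k = 1; k < horizon; ++k) { sum += zk * c[k]; zk *= z; }
      } else {
        double zn = std::pow(z, (double)(n - 1));
        sum = c[0] + zn * c[n - 1];
        double zk = z, zk2 = zn * zn / z; // z^(2n-3)
        for (R_xlen_t k = 1; k <= n - 2; ++k) {
          sum += (zk + zk2) * c[k];
          zk *= z; zk2 /= z;
        }
        sum /= (1.0 - zn * zn);
      }
      c[0] = sum;
      for (R_xlen_t i = 1; i < n; ++i) c[i] += z * c[i - 1];
      // anticausal init
      c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
      for (R_xlen_t i = n - 2; i >= 0; --i) {
        c[i] = z * (c[i + 1] - c[i]);
        if (i == 0) break;
      }
      for (R_xlen_t i = 0; i < n; ++i) s[i * stride] = c[i];
    }
}

inline std::vector<double> bspline3_coefficients(const double* v,
                                                 R_xlen_t nx, R_xlen_t ny,
                                                 R_xlen_t nz) {
  std::vector<double> c(v, v + nx * ny * nz);
  // along x: lines are (y,z) combos
  bspline3_prefilter_axis(c.data(), nx, 1, ny, nx, nz, nx * ny);
  // along y
  bspline3_prefilter_axis(c.data(), ny, nx, nx, 1, nz, nx * ny);
  // along z
  bspline3_prefilter_axis(c.data(), nz, nx * ny, nx, 1, ny, nx);
  return c;
}

#endif
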