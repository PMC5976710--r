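#include "core.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_apply_chain(List chainspec, NumericMatrix pts) {
  Chain ch = parse_chain(chainspec);
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  double p[3], q[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    p[0] = pts(i, 0); p[1] = pts(i, 1); p[2] = pts(i, 2);
    ch.apply(p, q);
    out(i, 0) = q[0]; out(i, 1) = q[1]; out(i, 2) = q[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector data, NumericMatrix idx,
                                int interp, double fill) {
  IntegerVector d = data.attr("dim");
  Grid3 g; g.v = REAL(data); g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  std::vector<double> coef;
  Grid3 gc = g;
  if (interp == 3) {
    coef = bspline3_coefficients(g.v, g.nx, g.ny, g.nz);
    gc.v = coef.data();
  }
  R_xlen_t n = idx.nrow();
  NumericVector out(n);
  double x[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    x[0] = idx(i, 0); x[1] = idx(i, 1); x[2] = idx(i, 2);
    if (!g.inside(x)) { out[i] = fill; continue; }
    if (interp == 0) out[i] = g.nearest(x);
    else if (interp == 1) out[i] = g.trilinear(x);
    else out[i] = gc.cubic(x);
  }
  return out;
}

// Resample/warp: out voxel (i,j,k) -> world (out_i2w) -> chain -> moving
// world -> continuous moving index (mov_w2i) -> interpolate.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector mov, NumericMatrix mov_w2i,
                       IntegerVector out_dims, NumericMatrix out_i2w,
                       List chainspec, int interp, double fill) {
  IntegerVector d = mov.attr("dim");
  Grid3 g; g.v = REAL(mov); g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  std::vector<double> coef;
  Grid3 gc = g;
  if (interp == 3) {
    coef = bspline3_coefficients(g.v, g.nx, g.ny, g.nz);
    gc.v = coef.data();
  }
  Chain ch = parse_chain(chainspec);
  Affine34 i2w = affine_from_matrix(out_i2w);
  Affine34 w2i = affine_from_matrix(mov_w2i);
  R_xlen_t nx = out_dims[0], ny = out_dims[1], nz = out_dims[2];
  NumericVector out(nx * ny * nz);
  out.attr("dim") = out_dims;
  double vi[3], w[3], mw[3], mi[3];
  R_xlen_t p = 0;
  for (R_xlen_t k = 0; k < nz; ++k)
    for (R_xlen_t j = 0; j < ny; ++j)
      for (R_xlen_t i = 0; i < nx; ++i, ++p) {
        vi[0] = (double)i; vi[1] = (double)j; vi[2] = (double)k;
        i2w.apply(vi, w);
        ch.apply(w, mw);
        w2i.apply(mw, mi);
        if (!g.inside(mi)) { out[p] = fill; continue; }
        if (interp == 0) out[p] = g.nearest(mi);
        else if (interp == 1) out[p] = g.trilinear(mi);
        else out[p] = gc.cubic(mi);
      }
  return out;
}

// ---- joint histogram with Maes-style partial-volume weighting -------------
//
// For each sample (fixed value f at fixed-space world point x) the mapped
// moving point distributes one unit of mass over the histogram rows of its
// 8 surrounding moving voxels with trilinear weights; the fixed bin is the
// bin of f. A sample contributes iff its mapped continuous index lies in
// [0, n-1]^3.

static inline int bin_of(double v, double lo, double hi, int bins) {
  if (hi <= lo) return 0;
  int b = (int)std::floor((v - lo) / (hi - lo) * bins);
  if (b < 0) b = 0;
  if (b >= bins) b = bins - 1;
  return b;
}

struct PVSample {
  double ix, iy, iz; // continuous moving index
  int bf;            // fixed bin
  bool inside;
};

static void pv_accumulate(const Grid3& g, double ix, double iy, double iz,
                          int bf, double sign, double* H, int bins,
                          double mlo, double mhi) {
  R_xlen_t i = (R_xlen_t)std::floor(ix);
  R_xlen_t j = (R_xlen_t)std::floor(iy);
  R_xlen_t k = (R_xlen_t)std::floor(iz);
  if (i >= g.nx - 1) i = g.nx - 2; if (i < 0) i = 0;
  if (j >= g.ny - 1) j = g.ny - 2; if (j < 0) j = 0;
  if (k >= g.nz - 1) k = g.nz - 2; if (k < 0) k = 0;
  double fx = ix - i, fy = iy - j, fz = iz - k;
  double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
  for (int c = 0; c < 2; ++c)
    for (int b = 0; b < 2; ++b)
      for (int a = 0; a < 2; ++a) {
        double w = wx[a] * wy[b] * wz[c];
        if (w == 0.0) continue;
        int bm = bin_of(g.at(i + a, j + b, k + c), mlo, mhi, bins);
        H[bf + bins * bm] += sign * w;
      }
}

static double nmi_of_hist(const double* H, int bins, double total) {
  if (total <= 0) return NA_REAL;
  double hx = 0, hy = 0, hxy = 0;
  std::vector<double> mx(bins, 0.0), my(bins, 0.0);
  for (int j = 0; j < bins; ++j)
    for (int i = 0; i < bins; ++i) {
      double p = H[i + bins * j];
      if (p > 0) {
        p /= total;
        hxy -= p * std::log2(p);
        mx[i] += p; my[j] += p;
      }
    }
  for (int i = 0; i < bins; ++i) {
    if (mx[i] > 0) hx -= mx[i] * std::log2(mx[i]);
    if (my[i] > 0) hy -= my[i] * std::log2(my[i]);
  }
  if (hxy <= 0) return 1.0; // single occupied cell: treat as fully dependent
  return (hx + hy) / hxy;
}

// Shared preparation: map samples, find contributing set and ranges.
static void prepare_samples(const NumericVector& fv, const NumericMatrix& pts,
                            const Chain& ch, const Affine34& w2i,
                            const Grid3& g, std::vector<PVSample>& smp,
                            double& flo, double& fhi, double& mlo, double& mhi,
                            bool auto_range) {
  R_xlen_t n = pts.nrow();
  smp.resize(n);
  bool first = true;
  double x[3], mw[3], mi[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    x[0] = pts(i, 0); x[1] = pts(i, 1); x[2] = pts(i, 2);
    ch.apply(x, mw);
    w2i.apply(mw, mi);
    PVSample& s = smp[i];
    s.ix = mi[0]; s.iy = mi[1]; s.iz = mi[2];
    s.inside = g.inside(mi);
    s.bf = -1;
    if (s.inside && auto_range) {
      double m = g.trilinear(mi);
      if (first) { flo = fhi = fv[i]; mlo = mhi = m; first = false; }
      else {
        if (fv[i] < flo) flo = fv[i]; if (fv[i] > fhi) fhi = fv[i];
        if (m < mlo) mlo = m; if (m > mhi) mhi = m;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_joint_hist(NumericVector fv, NumericMatrix pts, List chainspec,
                    NumericVector mov, NumericMatrix mov_w2i, int bins,
                    Nullable<NumericVector> fix_range,
                    Nullable<NumericVector> mov_range) {
  IntegerVector d = mov.attr("dim");
  Grid3 g; g.v = REAL(mov); g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  Chain ch = parse_chain(chainspec);
  Affine34 w2i = affine_from_matrix(mov_w2i);
  std::vector<PVSample> smp;
  double flo = 0, fhi = 0, mlo = 0, mhi = 0;
  bool auto_range = fix_range.isNull() || mov_range.isNull();
  prepare_samples(fv, pts, ch, w2i, g, smp, flo, fhi, mlo, mhi, auto_range);
  if (fix_range.isNotNull()) {
    NumericVector r(fix_range); flo = r[0]; fhi = r[1];
  }
  if (mov_range.isNotNull()) {
    NumericVector r(mov_range); mlo = r[0]; mhi = r[1];
  }
  NumericMatrix H(bins, bins);
  double* Hp = REAL(H);
  double total = 0;
  for (size_t i = 0; i < smp.size(); ++i) {
    if (!smp[i].inside) continue;
    int bf = bin_of(fv[i], flo, fhi, bins);
    pv_accumulate(g, smp[i].ix, smp[i].iy, smp[i].iz, bf, 1.0, Hp, bins,
                  mlo, mhi);
    total += 1.0;
  }
  return List::create(_["counts"] = H, _["n"] = total,
                      _["fix_range"] = NumericVector::create(flo, fhi),
                      _["mov_range"] = NumericVector::create(mlo, mhi));
}

// NMI of fixed samples vs moving image under a chain (frozen ranges).
// [[Rcpp::export]]
List cpp_nmi_chain(NumericVector fv, NumericMatrix pts, List chainspec,
                   NumericVector mov, NumericMatrix mov_w2i, int bins,
                   NumericVector fix_range, NumericVector mov_range) {
  IntegerVector d = mov.attr("dim");
  Grid3 g; g.v = REAL(mov); g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  Chain ch = parse_chain(chainspec);
  Affine34 w2i = affine_from_matrix(mov_w2i);
  std::vector<PVSample> smp;
  double flo = fix_range[0], fhi = fix_range[1];
  double mlo = mov_range[0], mhi = mov_range[1];
  double d1, d2, d3, d4;
  prepare_samples(fv, pts, ch, w2i, g, smp, d1, d2, d3, d4, false);
  std::vector<double> H(bins * bins, 0.0);
  double total = 0;
  for (size_t i = 0; i < smp.size(); ++i) {
    if (!smp[i].inside) continue;
    int bf = bin_of(fv[i], flo, fhi, bins);
    pv_accumulate(g, smp[i].ix, smp[i].iy, smp[i].iz, bf, 1.0, H.data(),
                  bins, mlo, mhi);
    total += 1.0;
  }
  return List::create(_["nmi"] = nmi_of_hist(H.data(), bins, total),
                      _["n"] = total);
}

// NMI and its forward-difference gradient w.r.t. B-spline control-point
// displacements. The chain is x -> x + d(x) -> P x (post affine). Perturbing
// coefficient (c, dim) by h moves a sample's moving index by
// h * w_c(x) * (W P e_dim), so only samples in the support of c are touched;
// the histogram is updated incrementally per control point.
// [[Rcpp::export]]
List cpp_bspline_nmi_grad(NumericVector fv, NumericMatrix pts,
                          NumericMatrix postM, NumericVector grid_origin,
                          NumericVector grid_spacing, IntegerVector grid_dims,
                          NumericVector coef, NumericVector mov,
                          NumericMatrix mov_w2i, int bins,
                          NumericVector fix_range, NumericVector mov_range,
                          double h) {
  IntegerVector d = mov.attr("dim");
  Grid3 g; g.v = REAL(mov); g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  Affine34 P = affine_from_matrix(postM);
  Affine34 w2i = affine_from_matrix(mov_w2i);
  const int gx = grid_dims[0], gy = grid_dims[1], gz = grid_dims[2];
  const R_xlen_t ncp = (R_xlen_t)gx * gy * gz;

  BsplineFFD B;
  for (int a = 0; a < 3; ++a) {
    B.origin[a] = grid_origin[a]; B.spacing[a] = grid_spacing[a];
    B.dims[a] = grid_dims[a];
  }
  B.coef = REAL(coef);

  const double flo = fix_range[0], fhi = fix_range[1];
  const double mlo = mov_range[0], mhi = mov_range[1];

  // index-space direction of a unit world perturbation along each axis,
  // composed with the post affine linear part
  double delta[3][3];
  for (int dim = 0; dim < 3; ++dim)
    for (int r = 0; r < 3; ++r)
      delta[dim][r] = w2i.m[4*r] * P.m[0*4 + dim] +
                      w2i.m[4*r+1] * P.m[1*4 + dim] +
                      w2i.m[4*r+2] * P.m[2*4 + dim];

  const R_xlen_t n = pts.nrow();
  std::vector<PVSample> smp(n);
  std::vector<double> ucoord(3 * n);     // lattice coordinates of samples
  std::vector<int> cell(n);              // linear base-cell id
  std::vector<double> H0(bins * bins, 0.0);
  double total0 = 0;

  double x[3], y[3], z[3], mi[3], dsp[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    x[0] = pts(i, 0); x[1] = pts(i, 1); x[2] = pts(i, 2);
    B.displacement(x, dsp);
    y[0] = x[0] + dsp[0]; y[1] = x[1] + dsp[1]; y[2] = x[2] + dsp[2];
    P.apply(y, z);
    w2i.apply(z, mi);
    PVSample& s = smp[i];
    s.ix = mi[0]; s.iy = mi[1]; s.iz = mi[2];
    s.inside = g.inside(mi);
    s.bf = bin_of(fv[i], flo, fhi, bins);
    int cc[3];
    for (int a = 0; a < 3; ++a) {
      double u = (x[a] - B.origin[a]) / B.spacing[a];
      ucoord[3 * i + a] = u;
      int c0 = (int)std::floor(u);
      int hi_cell = (a == 0 ? gx : (a == 1 ? gy : gz)) - 2;
      if (c0 < 0) c0 = 0;
      if (c0 > hi_cell) c0 = hi_cell;
      cc[a] = c0;
    }
    cell[i] = cc[0] + gx * (cc[1] + gy * cc[2]);
    if (s.inside) {
      pv_accumulate(g, s.ix, s.iy, s.iz, s.bf, 1.0, H0.data(), bins,
                    mlo, mhi);
      total0 += 1.0;
    }
  }
  double nmi0 = nmi_of_hist(H0.data(), bins, total0);

  // bucket samples by base cell
  std::vector<int> cnt(ncp, 0), start(ncp + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) cnt[cell[i]]++;
  for (R_xlen_t c = 0; c < ncp; ++c) start[c + 1] = start[c] + cnt[c];
  std::vector<int> order(n);
  { std::vector<int> pos(start.begin(), start.end() - 1);
    for (R_xlen_t i = 0; i < n; ++i) order[pos[cell[i]]++] = (int)i; }

  NumericVector grad(ncp * 3);
  std::vector<double> H(bins * bins);
  double newmi[3];

  for (int cz = 0; cz < gz; ++cz)
    for (int cy = 0; cy < gy; ++cy)
      for (int cx = 0; cx < gx; ++cx) {
        R_xlen_t cp = cx + (R_xlen_t)gx * (cy + (R_xlen_t)gy * cz);
        for (int dim = 0; dim < 3; ++dim) {
          std::copy(H0.begin(), H0.end(), H.begin());
          double total = total0;
          bool touched = false;
          // cells whose samples lie in the support of (cx,cy,cz)
          for (int bz = cz - 2; bz <= cz + 1; ++bz) {
            if (bz < 0 || bz > gz - 2) continue;
            for (int by = cy - 2; by <= cy + 1; ++by) {
              if (by < 0 || by > gy - 2) continue;
              for (int bx = cx - 2; bx <= cx + 1; ++bx) {
                if (bx < 0 || bx > gx - 2) continue;
                R_xlen_t cid = bx + (R_xlen_t)gx * (by + (R_xlen_t)gy * bz);
                for (int q = start[cid]; q < start[cid + 1]; ++q) {
                  int i = order[q];
                  double w = bspline3_kernel(ucoord[3*i] - cx) *
                             bspline3_kernel(ucoord[3*i+1] - cy) *
                             bspline3_kernel(ucoord[3*i+2] - cz);
                  if (w == 0.0) continue;
                  const PVSample& s = smp[i];
                  newmi[0] = s.ix + h * w * delta[dim][0];
                  newmi[1] = s.iy + h * w * delta[dim][1];
                  newmi[2] = s.iz + h * w * delta[dim][2];
                  bool ins_new = g.inside(newmi);
                  if (!s.inside && !ins_new) continue;
                  touched = true;
                  if (s.inside) {
                    pv_accumulate(g, s.ix, s.iy, s.iz, s.bf, -1.0, H.data(),
                                  bins, mlo, mhi);
                    total -= 1.0;
                  }
                  if (ins_new) {
                    pv_accumulate(g, newmi[0], newmi[1], newmi[2], s.bf, 1.0,
                                  H.data(), bins, mlo, mhi);
                    total += 1.0;
                  }
                }
              }
            }
          }
          grad[cp + ncp * dim] = touched ?
            (nmi_of_hist(H.data(), bins, total) - nmi0) / h : 0.0;
        }
      }
  grad.attr("dim") = IntegerVector::create(gx, gy, gz, 3);
  return List::create(_["nmi"] = nmi0, _["n"] = total0, _["grad"] = grad);
}

// separable Gaussian smoothing, reflected boundaries, sigma in voxels
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector data, NumericVector sigma) {
  IntegerVector d = data.attr("dim");
  R_xlen_t nx = d[0], ny = d[1], nz = d[2];
  std::vector<double> a(REAL(data), REAL(data) + nx * ny * nz), b(a.size());
  R_xlen_t n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r];
    }
    for (size_t i = 0; i < k.size(); ++i) k[i] /= sum;
    R_xlen_t o1 = stride[(ax + 1) % 3], n1 = n[(ax + 1) % 3];
    R_xlen_t o2 = stride[(ax + 2) % 3], n2 = n[(ax + 2) % 3];
    R_xlen_t st = stride[ax], len = n[ax];
    for (R_xlen_t j2 = 0; j2 < n2; ++j2)
      for (R_xlen_t j1 = 0; j1 < n1; ++j1) {
        R_xlen_t base = j1 * o1 + j2 * o2;
        for (R_xlen_t i = 0; i < len; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            R_xlen_t ii = i + t;
            if (ii < 0) ii = -ii;
            if (ii >= len) ii = 2 * (len - 1) - ii;
            acc += k[t + r] * a[base + ii * st];
          }
          b[base + i * st] = acc;
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}
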