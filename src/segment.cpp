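#include "core.h"
#include <queue>
#include <limits>
using namespace Rcpp;

// ---- Perona-Malik anisotropic diffusion -----------------------------------
// Explicit update over the 6 face neighbours with conductance
// g(s) = exp(-(s/kappa)^2) evaluated on one-sided differences (voxel units),
// Neumann (zero-flux) boundaries.
// [[Rcpp::export]]
NumericVector cpp_diffusion(NumericVector data, int iterations, double kappa,
                            double dt) {
  IntegerVector d = data.attr("dim");
  R_xlen_t nx = d[0], ny = d[1], nz = d[2];
  std::vector<double> a(REAL(data), REAL(data) + nx * ny * nz), b(a.size());
  const R_xlen_t sx = 1, sy = nx, sz = nx * ny;
  for (int it = 0; it < iterations; ++it) {
    R_xlen_t p = 0;
    for (R_xlen_t k = 0; k < nz; ++k)
      for (R_xlen_t j = 0; j < ny; ++j)
        for (R_xlen_t i = 0; i < nx; ++i, ++p) {
          double c = a[p], flux = 0.0, df;
          if (i + 1 < nx) { df = a[p + sx] - c;
            flux += std::exp(-(df / kappa) * (df / kappa)) * df; }
          if (i > 0)      { df = a[p - sx] - c;
            flux += std::exp(-(df / kappa) * (df / kappa)) * df; }
          if (j + 1 < ny) { df = a[p + sy] - c;
            flux += std::exp(-(df / kappa) * (df / kappa)) * df; }
          if (j > 0)      { df = a[p - sy] - c;
            flux += std::exp(-(df / kappa) * (df / kappa)) * df; }
          if (k + 1 < nz) { df = a[p + sz] - c;
            flux += std::exp(-(df / kappa) * (df / kappa)) * df; }
          if (k > 0)      { df = a[p - sz] - c;
            flux += std::exp(-(df / kappa) * (df / kappa)) * df; }
          b[p] = c + dt * flux;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}

// ---- fast marching --------------------------------------------------------
// First-arrival times T solving |grad T| * speed = 1 from seed voxels,
// first-order upwind discretisation on the 6-neighbour stencil with
// anisotropic spacing, binary-heap front with lazy deletion.

struct HeapNode {
  double t; R_xlen_t idx;
  bool operator>(const HeapNode& o) const { return t > o.t; }
};

static double eikonal_solve(const double* T, const signed char* state,
                            R_xlen_t p, R_xlen_t i, R_xlen_t j, R_xlen_t k,
                            R_xlen_t nx, R_xlen_t ny, R_xlen_t nz,
                            const double* h, double f) {
  double a[6]; int na = 0; // up to 3 (arrival, spacing) pairs
  const R_xlen_t s[3] = {1, nx, nx * ny};
  const R_xlen_t pos[3] = {i, j, k};
  const R_xlen_t lim[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double best = std::numeric_limits<double>::infinity();
    if (pos[ax] > 0 && state[p - s[ax]] == 2) best = T[p - s[ax]];
    if (pos[ax] + 1 < lim[ax] && state[p + s[ax]] == 2 && T[p + s[ax]] < best)
      best = T[p + s[ax]];
    if (std::isfinite(best)) { a[na] = best; a[na + 1] = h[ax]; na += 2; }
  }
  // solve sum_d max(0, (t - a_d)/h_d)^2 = 1/f^2 over available axes,
  // dropping axes whose a_d exceeds the trial solution
  int m = na / 2;
  // sort pairs by arrival value
  for (int x = 0; x < m; ++x)
    for (int y = x + 1; y < m; ++y)
      if (a[2 * y] < a[2 * x]) {
        std::swap(a[2 * x], a[2 * y]); std::swap(a[2 * x + 1], a[2 * y + 1]);
      }
  double rhs = 1.0 / (f * f);
  for (int use = m; use >= 1; --use) {
    double A = 0, B = 0, C = -rhs;
    for (int x = 0; x < use; ++x) {
      double w = 1.0 / (a[2 * x + 1] * a[2 * x + 1]);
      A += w; B -= 2.0 * a[2 * x] * w; C += a[2 * x] * a[2 * x] * w;
    }
    double disc = B * B - 4 * A * C;
    if (disc >= 0) {
      double t = (-B + std::sqrt(disc)) / (2 * A);
      if (t >= a[2 * (use - 1)]) // causal: not below the largest used arrival
        return t;
    }
  }
  return a[0] + a[1] / f; // 1D fallback
}

// [[Rcpp::export]]
NumericVector cpp_fast_marching(NumericVector speed, NumericVector spacing,
                                IntegerMatrix seeds) {
  IntegerVector d = speed.attr("dim");
  R_xlen_t nx = d[0], ny = d[1], nz = d[2], N = nx * ny * nz;
  const double* f = REAL(speed);
  double h[3] = {spacing[0], spacing[1], spacing[2]};
  NumericVector Tout(N);
  Tout.attr("dim") = d;
  double* T = REAL(Tout);
  std::vector<signed char> state(N, 0); // 0 far, 1 trial, 2 accepted
  for (R_xlen_t p = 0; p < N; ++p) T[p] = R_PosInf;
  std::priority_queue<HeapNode, std::vector<HeapNode>, std::greater<HeapNode> > pq;
  // high-accuracy initialisation: the point-source singularity dominates the
  // first-order scheme, so seed a small exact near field (local speed)
  const int r0 = 3;
  for (int s = 0; s < seeds.nrow(); ++s) {
    R_xlen_t si = seeds(s, 0), sj = seeds(s, 1), sk = seeds(s, 2);
    R_xlen_t sp = si + nx * (sj + ny * sk);
    double fs = f[sp];
    for (int dk = -r0; dk <= r0; ++dk)
      for (int dj = -r0; dj <= r0; ++dj)
        for (int di = -r0; di <= r0; ++di) {
          R_xlen_t i = si + di, j = sj + dj, k = sk + dk;
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
            continue;
          double dist = std::sqrt(di * h[0] * di * h[0] +
                                  dj * h[1] * dj * h[1] +
                                  dk * h[2] * dk * h[2]);
          R_xlen_t p = i + nx * (j + ny * k);
          double t = dist / fs;
          if (t < T[p]) {
            T[p] = t; state[p] = 1;
            pq.push(HeapNode{t, p});
          }
        }
  }
  const R_xlen_t st[3] = {1, nx, nx * ny};
  while (!pq.empty()) {
    HeapNode nd = pq.top(); pq.pop();
    if (state[nd.idx] == 2 || nd.t > T[nd.idx]) continue;
    state[nd.idx] = 2;
    R_xlen_t p = nd.idx;
    R_xlen_t i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
    const R_xlen_t pos[3] = {i, j, k};
    const R_xlen_t lim[3] = {nx, ny, nz};
    for (int ax = 0; ax < 3; ++ax)
      for (int dir = -1; dir <= 1; dir += 2) {
        if ((dir < 0 && pos[ax] == 0) || (dir > 0 && pos[ax] + 1 == lim[ax]))
          continue;
        R_xlen_t q = p + dir * st[ax];
        if (state[q] == 2) continue;
        R_xlen_t qi = q % nx, qj = (q / nx) % ny, qk = q / (nx * ny);
        double t = eikonal_solve(T, state.data(), q, qi, qj, qk, nx, ny, nz,
                                 h, f[q]);
        if (t < T[q]) {
          T[q] = t; state[q] = 1;
          pq.push(HeapNode{t, q});
        }
      }
  }
  return Tout;
}

// ---- exact Euclidean distance transform (Felzenszwalb-Huttenlocher) -------
// Squared distances to the nearest site voxel, anisotropic spacing in mm.

static void edt_1d(const double* fin, double* dout, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> zbuf(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zbuf[0] = -INF; zbuf[1] = INF;
  auto intersect = [&](int q, int p) {
    double xq = q * h, xp = p * h;
    return ((fin[q] + xq * xq) - (fin[p] + xp * xp)) / (2 * xq - 2 * xp);
  };
  for (int q = 1; q < n; ++q) {
    double s = intersect(q, v[k]);
    while (k > 0 && s <= zbuf[k]) {
      --k;
      s = intersect(q, v[k]);
    }
    ++k; v[k] = q; zbuf[k] = s; zbuf[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (zbuf[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    dout[q] = dx * dx + fin[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sites, NumericVector spacing) {
  IntegerVector d = sites.attr("dim");
  R_xlen_t nx = d[0], ny = d[1], nz = d[2], N = nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> D(N);
  for (R_xlen_t p = 0; p < N; ++p) D[p] = sites[p] ? 0.0 : INF;
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  std::vector<double> out(line.size());
  // x pass
  for (R_xlen_t k = 0; k < nz; ++k)
    for (R_xlen_t j = 0; j < ny; ++j) {
      R_xlen_t base = nx * (j + ny * k);
      for (R_xlen_t i = 0; i < nx; ++i) line[i] = D[base + i];
      edt_1d(line.data(), out.data(), (int)nx, spacing[0]);
      for (R_xlen_t i = 0; i < nx; ++i) D[base + i] = out[i];
    }
  // y pass
  for (R_xlen_t k = 0; k < nz; ++k)
    for (R_xlen_t i = 0; i < nx; ++i) {
      R_xlen_t base = i + nx * ny * k;
      for (R_xlen_t j = 0; j < ny; ++j) line[j] = D[base + nx * j];
      edt_1d(line.data(), out.data(), (int)ny, spacing[1]);
      for (R_xlen_t j = 0; j < ny; ++j) D[base + nx * j] = out[j];
    }
  // z pass
  for (R_xlen_t j = 0; j < ny; ++j)
    for (R_xlen_t i = 0; i < nx; ++i) {
      R_xlen_t base = i + nx * j;
      for (R_xlen_t k = 0; k < nz; ++k) line[k] = D[base + nx * ny * k];
      edt_1d(line.data(), out.data(), (int)nz, spacing[2]);
      for (R_xlen_t k = 0; k < nz; ++k) D[base + nx * ny * k] = out[k];
    }
  NumericVector res(D.begin(), D.end());
  res.attr("dim") = d;
  return res;
}

// ---- 6-connected components ----------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  R_xlen_t nx = d[0], ny = d[1], nz = d[2], N = nx * ny * nz;
  IntegerVector lab(N);
  lab.attr("dim") = d;
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t st[3] = {1, nx, nx * ny};
  for (R_xlen_t p0 = 0; p0 < N; ++p0) {
    if (!mask[p0] || lab[p0] != 0) continue;
    lab[p0] = ++next;
    stack.push_back(p0);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      R_xlen_t i = p % nx, j = (p / nx) % ny, k = p / (nx * ny);
      const R_xlen_t pos[3] = {i, j, k};
      const R_xlen_t lim[3] = {nx, ny, nz};
      for (int ax = 0; ax < 3; ++ax)
        for (int dir = -1; dir <= 1; dir += 2) {
          if ((dir < 0 && pos[ax] == 0) || (dir > 0 && pos[ax] + 1 == lim[ax]))
            continue;
          R_xlen_t q = p + dir * st[ax];
          if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
        }
    }
  }
  return lab;
}

// ---- geodesic active contour level-set evolution --------------------------
// phi < 0 inside. Outward normal speed F = g * (prop - curv * kappa) plus
// edge-attraction advection with velocity -adv * grad g:
//   phi_t = -F |grad phi|_godunov + adv * grad g . grad phi (upwind).
// Gradients in mm. Returns updated phi after `iterations` explicit steps of
// size dt, or earlier once the RMS phi change per step drops below tol.
// [[Rcpp::export]]
List cpp_gac_evolve(NumericVector phi0, NumericVector gmap,
                    NumericVector gradg_x, NumericVector gradg_y,
                    NumericVector gradg_z, NumericVector spacing,
                    double prop, double curv, double adv,
                    int iterations, double dt, double tol, double band) {
  IntegerVector d = phi0.attr("dim");
  R_xlen_t nx = d[0], ny = d[1], nz = d[2], N = nx * ny * nz;
  std::vector<double> phi(REAL(phi0), REAL(phi0) + N), nphi(N);
  const double* gg = REAL(gmap);
  const double* gx = REAL(gradg_x);
  const double* gy = REAL(gradg_y);
  const double* gz = REAL(gradg_z);
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const R_xlen_t sx = 1, sy = nx, sz = nx * ny;
  int used = 0;
  double rms = R_PosInf;
  for (int it = 0; it < iterations; ++it) {
    double sumsq = 0;
    R_xlen_t p = 0;
    for (R_xlen_t k = 0; k < nz; ++k)
      for (R_xlen_t j = 0; j < ny; ++j)
        for (R_xlen_t i = 0; i < nx; ++i, ++p) {
          double c = phi[p];
          // narrow band: only voxels near the zero level evolve
          if (std::fabs(c) > band) { nphi[p] = c; continue; }
          // one-sided differences (Neumann at faces)
          double dxm = i > 0 ? (c - phi[p - sx]) / hx : 0.0;
          double dxp = i + 1 < nx ? (phi[p + sx] - c) / hx : 0.0;
          double dym = j > 0 ? (c - phi[p - sy]) / hy : 0.0;
          double dyp = j + 1 < ny ? (phi[p + sy] - c) / hy : 0.0;
          double dzm = k > 0 ? (c - phi[p - sz]) / hz : 0.0;
          double dzp = k + 1 < nz ? (phi[p + sz] - c) / hz : 0.0;
          // mean curvature from central differences
          double cx = 0.5 * (dxm + dxp), cy = 0.5 * (dym + dyp),
                 cz = 0.5 * (dzm + dzp);
          double gmag2 = cx * cx + cy * cy + cz * cz;
          double kap = 0.0;
          if (gmag2 > 1e-12) {
            double pxx = (dxp - dxm) / hx, pyy = (dyp - dym) / hy,
                   pzz = (dzp - dzm) / hz;
            double pxy = 0, pxz = 0, pyz = 0;
            if (i > 0 && i + 1 < nx && j > 0 && j + 1 < ny)
              pxy = (phi[p + sx + sy] - phi[p + sx - sy] - phi[p - sx + sy] +
                     phi[p - sx - sy]) / (4 * hx * hy);
            if (i > 0 && i + 1 < nx && k > 0 && k + 1 < nz)
              pxz = (phi[p + sx + sz] - phi[p + sx - sz] - phi[p - sx + sz] +
                     phi[p - sx - sz]) / (4 * hx * hz);
            if (j > 0 && j + 1 < ny && k > 0 && k + 1 < nz)
              pyz = (phi[p + sy + sz] - phi[p + sy - sz] - phi[p - sy + sz] +
                     phi[p - sy - sz]) / (4 * hy * hz);
            double num = (pyy + pzz) * cx * cx + (pxx + pzz) * cy * cy +
                         (pxx + pyy) * cz * cz -
                         2 * (cx * cy * pxy + cx * cz * pxz + cy * cz * pyz);
            kap = num / (2.0 * std::pow(gmag2, 1.5));
            // clamp curvature to the grid scale for stability
            double kmax = 1.0 / std::min(hx, std::min(hy, hz));
            if (kap > kmax) kap = kmax;
            if (kap < -kmax) kap = -kmax;
          }
          double F = gg[p] * (prop - curv * kap);
          // Godunov upwind |grad phi| for motion with speed F (phi_t = -F|.|)
          double gpl, upd;
          if (F > 0) {
            double ax2 = std::max(dxm, 0.0), bx = std::min(dxp, 0.0);
            double ay = std::max(dym, 0.0), by = std::min(dyp, 0.0);
            double az = std::max(dzm, 0.0), bz = std::min(dzp, 0.0);
            gpl = std::sqrt(std::max(ax2 * ax2, bx * bx) +
                            std::max(ay * ay, by * by) +
                            std::max(az * az, bz * bz));
          } else {
            double ax2 = std::min(dxm, 0.0), bx = std::max(dxp, 0.0);
            double ay = std::min(dym, 0.0), by = std::max(dyp, 0.0);
            double az = std::min(dzm, 0.0), bz = std::max(dzp, 0.0);
            gpl = std::sqrt(std::max(ax2 * ax2, bx * bx) +
                            std::max(ay * ay, by * by) +
                            std::max(az * az, bz * bz));
          }
          upd = -F * gpl;
          // advection with velocity v = -adv * grad g (upwind per component)
          if (adv != 0.0) {
            double vx = -adv * gx[p], vy = -adv * gy[p], vz = -adv * gz[p];
            upd -= vx * (vx > 0 ? dxm : dxp) + vy * (vy > 0 ? dym : dyp) +
                   vz * (vz > 0 ? dzm : dzp);
          }
          double nv = c + dt * upd;
          if (nv > band) nv = band;
          if (nv < -band) nv = -band;
          nphi[p] = nv;
          sumsq += (nv - c) * (nv - c);
        }
    phi.swap(nphi);
    ++used;
    rms = std::sqrt(sumsq / (double)N);
    if (rms < tol) break;
  }
  NumericVector out(phi.begin(), phi.end());
  out.attr("dim") = d;
  return List::create(_["phi"] = out, _["iterations"] = used,
                      _["rms_change"] = rms);
}
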