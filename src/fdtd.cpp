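// Explicit FDTD kernels for the Westervelt equation
//
//   lap(p) - p_tt/c^2 + (delta/c^4) p_ttt + (beta/(rho c^4)) (p^2)_tt = 0
//
// rearranged to p_tt = c^2 lap(p) + (delta/c^2) p_ttt + (beta/(rho c^2)) (p^2)_tt
// and advanced with a three-level leapfrog:
//   * spatial operator: in uniform-material regions an isotropic-error
//     2nd-order stencil (9-point in the r-z plane, 27-point in 3-D) whose
//     leading dispersion error is direction-independent; at material
//     interfaces the conservative heterogeneous form rho grad.(1/rho grad p)
//     with face-averaged inverse densities, so pressure transmission follows
//     the impedance (rho c) contrast
//   * the caller passes a "simulation" sound speed (dispersion-tuned so the
//     numerical phase speed at the drive frequency equals the physical one;
//     densities are inversely tuned so impedances stay physical); the
//     physical c enters only the nonlinear coefficient
//   * loss term: delta * dt * (lap^n - lap^{n-1}), a backward difference in
//     time (the thermoviscous (delta/c^2) p_ttt after substituting
//     p_tt ~ c^2 lap p); its half-step lag partially offsets residual
//     dispersion in the decay rate
//   * nonlinear term: backward 2nd difference of p^2 over the three stored
//     levels (keeps the update explicit)
// Boundaries: first-order Mur one-way condition with the local sound speed;
// the r = 0 axis of the cylindrical grid uses the regularity condition
// (1/r) dp/dr -> d2p/dr2.
//
// Sources are "hard": the drive p0 sin(omega t) overwrites pressure on the
// source cells after each update.  Per-cell steady-state amplitude is the
// running max |p| over two user-given step windows (two consecutive drive
// cycles), so callers can form both max(A,B) and a convergence residual.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void check_finite(double m, int step) {
  if (!std::isfinite(m))
    stop("FDTD divergence: non-finite pressure at step %d", step);
}

// flush tiny values to zero: denormalized numbers in the quiet regions of
// the domain otherwise dominate runtime on x86
static inline double flush(double v) {
  return (v > -1e-100 && v < 1e-100) ? 0.0 : v;
}

static inline bool close_rel(double a, double b) {
  return std::fabs(a - b) <= 1e-9 * (std::fabs(a) + std::fabs(b));
}

// ---------------------------------------------------------------- 1-D kernel
// [[Rcpp::export]]
List fdtd_run_1d(NumericVector c_map, NumericVector rho_map,
                 NumericVector delta_map, NumericVector beta_map,
                 double dx, double dt,
                 int src_idx, double src_amp, double omega,
                 int nsteps, IntegerVector probe_idx,
                 int recA0, int recA1, int recB0, int recB1,
                 bool nonlinear, bool soft_src, double blowup) {
  const int n = c_map.size();
  const double invdx2 = 1.0 / (dx * dx);
  std::vector<double> A(n), B(n), C(n), ir(n);
  for (int i = 0; i < n; ++i) {
    A[i] = c_map[i] * c_map[i] * dt * dt;
    B[i] = delta_map[i] * dt;
    C[i] = nonlinear ? beta_map[i] / (rho_map[i] * c_map[i] * c_map[i]) : 0.0;
    ir[i] = 1.0 / rho_map[i];
  }
  std::vector<double> pn(n, 0.0), pc(n, 0.0), pm(n, 0.0), pm2(n, 0.0);
  std::vector<double> lap(n, 0.0), lapprev(n, 0.0);
  const int np = probe_idx.size();
  NumericMatrix probes(nsteps, np);
  NumericVector ampA(n), ampB(n);
  std::vector<double> loA(n, 1e300), hiA(n, -1e300), loB(n, 1e300), hiB(n, -1e300);

  for (int s = 0; s < nsteps; ++s) {
    double mx = 0.0;
    for (int i = 1; i < n - 1; ++i) {
      const double wE = 0.5 + 0.5 * rho_map[i] * ir[i + 1];
      const double wW = 0.5 + 0.5 * rho_map[i] * ir[i - 1];
      const double L = (wE * (pc[i + 1] - pc[i]) +
                        wW * (pc[i - 1] - pc[i])) * invdx2;
      lap[i] = L;
      double v = 2.0 * pc[i] - pm[i] + A[i] * L + B[i] * (L - lapprev[i]);
      if (C[i] != 0.0)
        v += C[i] * (pc[i] * pc[i] - 2.0 * pm[i] * pm[i] + pm2[i] * pm2[i]);
      pn[i] = flush(v);
    }
    { // Mur faces
      const double m0 = (c_map[0] * dt - dx) / (c_map[0] * dt + dx);
      pn[0] = pc[1] + m0 * (pn[1] - pc[0]);
      const double m1 = (c_map[n - 1] * dt - dx) / (c_map[n - 1] * dt + dx);
      pn[n - 1] = pc[n - 2] + m1 * (pn[n - 2] - pc[n - 1]);
    }
    if (src_amp != 0.0) {
      const double drive = src_amp * std::sin(omega * (s + 1) * dt);
      if (soft_src) pn[src_idx] += drive; else pn[src_idx] = drive;
    }

    for (int k = 0; k < np; ++k) probes(s, k) = pn[probe_idx[k]];
    const bool inA = (s >= recA0 && s < recA1), inB = (s >= recB0 && s < recB1);
    for (int i = 0; i < n; ++i) {
      const double v = pn[i], a = std::fabs(v);
      if (a > mx) mx = a;
      if (inA) { if (v > hiA[i]) hiA[i] = v; if (v < loA[i]) loA[i] = v; }
      if (inB) { if (v > hiB[i]) hiB[i] = v; if (v < loB[i]) loB[i] = v; }
    }
    check_finite(mx, s);
    if (mx > blowup) stop("FDTD divergence: |p| exceeded %g at step %d", blowup, s);
    std::swap(lapprev, lap);
    pm2.swap(pm); pm.swap(pc); pc.swap(pn);
  }
  for (int i = 0; i < n; ++i) {
    ampA[i] = hiA[i] > loA[i] ? 0.5 * (hiA[i] - loA[i]) : 0.0;
    ampB[i] = hiB[i] > loB[i] ? 0.5 * (hiB[i] - loB[i]) : 0.0;
  }
  return List::create(_["probes"] = probes, _["ampA"] = ampA, _["ampB"] = ampB);
}

// ------------------------------------------------------ axisymmetric kernel
// Grids are (nr x nz) matrices, r_i = i*dx (i = 0 on the beam axis),
// z_j = j*dx.  Mur faces: i = nr-1, j = 0, j = nz-1.
// csim: dispersion-tuned speed; c_map: physical speed (nonlinear coeff).
// [[Rcpp::export]]
List fdtd_run_axi(NumericMatrix csim, NumericMatrix c_map,
                  NumericMatrix rho_map, NumericMatrix delta_map,
                  NumericMatrix beta_map,
                  double dx, double dt,
                  IntegerVector src_i, IntegerVector src_j,
                  NumericVector src_phase,
                  double src_amp, double omega,
                  int nsteps, int recA0, int recA1, int recB0, int recB1,
                  bool nonlinear, double blowup) {
  const int nr = c_map.nrow(), nz = c_map.ncol();
  const int N = nr * nz;
  const double invdx2 = 1.0 / (dx * dx);
  std::vector<double> A(N), B(N), C(N), ir(N);
  for (int k = 0; k < N; ++k) {
    A[k] = csim[k] * csim[k] * dt * dt;
    B[k] = delta_map[k] * dt;
    C[k] = nonlinear ? beta_map[k] / (rho_map[k] * c_map[k] * c_map[k]) : 0.0;
    ir[k] = csim[k] / (rho_map[k] * c_map[k]);  // 1 / rho_eff, Z preserved
  }
  // uniform-material flag for the isotropic stencil (8-neighbourhood)
  std::vector<char> uni(N, 0);
  for (int j = 1; j < nz - 1; ++j)
    for (int i = 1; i < nr - 1; ++i) {
      const int k = j * nr + i;
      bool u = true;
      for (int dj = -1; dj <= 1 && u; ++dj)
        for (int di = -1; di <= 1 && u; ++di)
          u = close_rel(A[k], A[k + dj * nr + di]) &&
              close_rel(ir[k], ir[k + dj * nr + di]);
      uni[k] = u;
    }
  // conservative stencil in a 2-cell halo around the clamped source surface
  for (int q = 0; q < src_i.size(); ++q)
    for (int dj = -2; dj <= 2; ++dj)
      for (int di = -2; di <= 2; ++di) {
        const int ii = src_i[q] + di, jj = src_j[q] + dj;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nz) uni[jj * nr + ii] = 0;
      }
  std::vector<double> pn(N, 0.0), pc(N, 0.0), pm(N, 0.0), pm2(N, 0.0);
  std::vector<double> lap(N, 0.0), lapprev(N, 0.0);
  NumericMatrix ampA(nr, nz), ampB(nr, nz);
  std::vector<double> loA(N, 1e300), hiA(N, -1e300), loB(N, 1e300), hiB(N, -1e300);
  const int ns = src_i.size();

  for (int s = 0; s < nsteps; ++s) {
    double mx = 0.0;
    for (int j = 1; j < nz - 1; ++j) {
      const int o = j * nr, oN = o + nr, oS = o - nr;
      { // axis cell i = 0: lap = 4 (p1 - p0)/dx^2 + d2p/dz2
        const int k = o;
        const double rr = rho_map[k] * c_map[k];  // rho_eff = rr / csim
        const double wE = 0.5 + 0.5 * (rr / csim[k]) * ir[k + 1];
        const double wN = 0.5 + 0.5 * (rr / csim[k]) * ir[oN];
        const double wS = 0.5 + 0.5 * (rr / csim[k]) * ir[oS];
        const double L = (4.0 * wE * (pc[k + 1] - pc[k]) +
                          wN * (pc[oN] - pc[k]) +
                          wS * (pc[oS] - pc[k])) * invdx2;
        lap[k] = L;
        double v = 2.0 * pc[k] - pm[k] + A[k] * L + B[k] * (L - lapprev[k]);
        if (C[k] != 0.0)
          v += C[k] * (pc[k] * pc[k] - 2.0 * pm[k] * pm[k] + pm2[k] * pm2[k]);
        pn[k] = flush(v);
      }
      for (int i = 1; i < nr - 1; ++i) {
        const int k = o + i;
        double L;
        if (uni[k]) {
          L = (((4.0 * (pc[k + 1] + pc[k - 1] + pc[oN + i] + pc[oS + i]) +
                 pc[oN + i + 1] + pc[oN + i - 1] +
                 pc[oS + i + 1] + pc[oS + i - 1] - 20.0 * pc[k]) / 6.0) +
               (pc[k + 1] - pc[k - 1]) / (2.0 * i)) * invdx2;
        } else {
          const double re = rho_map[k] * c_map[k] / csim[k];  // rho_eff
          const double fE = (i + 0.5) / i, fW = (i - 0.5) / i;
          const double wE = (0.5 + 0.5 * re * ir[k + 1]) * fE;
          const double wW = (0.5 + 0.5 * re * ir[k - 1]) * fW;
          const double wN = 0.5 + 0.5 * re * ir[oN + i];
          const double wS = 0.5 + 0.5 * re * ir[oS + i];
          L = (wE * (pc[k + 1] - pc[k]) +
               wW * (pc[k - 1] - pc[k]) +
               wN * (pc[oN + i] - pc[k]) +
               wS * (pc[oS + i] - pc[k])) * invdx2;
        }
        lap[k] = L;
        double v = 2.0 * pc[k] - pm[k] + A[k] * L + B[k] * (L - lapprev[k]);
        if (C[k] != 0.0)
          v += C[k] * (pc[k] * pc[k] - 2.0 * pm[k] * pm[k] + pm2[k] * pm2[k]);
        pn[k] = flush(v);
      }
    }
    // Mur faces (local tuned sound speed)
    for (int j = 1; j < nz - 1; ++j) { // outer radius
      const int k = j * nr + (nr - 1);
      const double m = (csim[k] * dt - dx) / (csim[k] * dt + dx);
      pn[k] = pc[k - 1] + m * (pn[k - 1] - pc[k]);
    }
    for (int i = 0; i < nr; ++i) { // z = 0 face
      const double m = (csim[i] * dt - dx) / (csim[i] * dt + dx);
      pn[i] = pc[i + nr] + m * (pn[i + nr] - pc[i]);
    }
    for (int i = 0; i < nr; ++i) { // z = max face
      const int k = (nz - 1) * nr + i;
      const double m = (csim[k] * dt - dx) / (csim[k] * dt + dx);
      pn[k] = pc[k - nr] + m * (pn[k - nr] - pc[k]);
    }
    { // radial corners: axial one-way update
      int k = nr - 1;
      double m = (csim[k] * dt - dx) / (csim[k] * dt + dx);
      pn[k] = pc[k + nr] + m * (pn[k + nr] - pc[k]);
      k = nz * nr - 1;
      m = (csim[k] * dt - dx) / (csim[k] * dt + dx);
      pn[k] = pc[k - nr] + m * (pn[k - nr] - pc[k]);
    }
    if (src_amp != 0.0) {
      const double t = omega * (s + 1) * dt;
      for (int q = 0; q < ns; ++q)
        pn[src_j[q] * nr + src_i[q]] = src_amp * std::sin(t + src_phase[q]);
    }
    const bool inA = (s >= recA0 && s < recA1), inB = (s >= recB0 && s < recB1);
    for (int k = 0; k < N; ++k) {
      const double v = pn[k], a = std::fabs(v);
      if (a > mx) mx = a;
      if (inA) { if (v > hiA[k]) hiA[k] = v; if (v < loA[k]) loA[k] = v; }
      if (inB) { if (v > hiB[k]) hiB[k] = v; if (v < loB[k]) loB[k] = v; }
    }
    check_finite(mx, s);
    if (mx > blowup) stop("FDTD divergence: |p| exceeded %g at step %d", blowup, s);
    std::swap(lapprev, lap);
    pm2.swap(pm); pm.swap(pc); pc.swap(pn);
  }
  for (int k = 0; k < N; ++k) {
    ampA[k] = hiA[k] > loA[k] ? 0.5 * (hiA[k] - loA[k]) : 0.0;
    ampB[k] = hiB[k] > loB[k] ? 0.5 * (hiB[k] - loB[k]) : 0.0;
  }
  return List::create(_["ampA"] = ampA, _["ampB"] = ampB);
}

// --------------------------------------------------------------- 3-D kernel
// Cartesian (nx, ny, nz) grids flattened column-major (x fastest).
// [[Rcpp::export]]
List fdtd_run_3d(NumericVector csim, NumericVector c_map,
                 NumericVector rho_map, NumericVector delta_map,
                 NumericVector beta_map,
                 IntegerVector dims, double dx, double dt,
                 IntegerVector src_lin, NumericVector src_phase,
                 double src_amp, double omega,
                 int nsteps, int recA0, int recA1, int recB0, int recB1,
                 bool nonlinear, double blowup) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz, sx = 1, sy = nx, sz = nx * ny;
  const double invdx2 = 1.0 / (dx * dx);
  // 27-point isotropic weights
  const double wf = 7.0 / 15.0, we = 1.0 / 10.0, wc = 1.0 / 30.0,
               w0 = 64.0 / 15.0;
  std::vector<double> A(N), B(N), C(N), ir(N);
  for (int k = 0; k < N; ++k) {
    A[k] = csim[k] * csim[k] * dt * dt;
    B[k] = delta_map[k] * dt;
    C[k] = nonlinear ? beta_map[k] / (rho_map[k] * c_map[k] * c_map[k]) : 0.0;
    ir[k] = csim[k] / (rho_map[k] * c_map[k]);
  }
  std::vector<char> uni(N, 0);
  for (int kz = 1; kz < nz - 1; ++kz)
    for (int ky = 1; ky < ny - 1; ++ky)
      for (int kx = 1; kx < nx - 1; ++kx) {
        const int k = kz * sz + ky * sy + kx;
        bool u = true;
        for (int a = -1; a <= 1 && u; ++a)
          for (int b = -1; b <= 1 && u; ++b)
            for (int c = -1; c <= 1 && u; ++c)
              u = close_rel(A[k], A[k + a * sz + b * sy + c]) &&
                  close_rel(ir[k], ir[k + a * sz + b * sy + c]);
        uni[k] = u;
      }
  std::vector<double> pn(N, 0.0), pc(N, 0.0), pm(N, 0.0), pm2(N, 0.0);
  std::vector<double> lap(N, 0.0), lapprev(N, 0.0);
  NumericVector ampA(N), ampB(N);
  std::vector<double> loA(N, 1e300), hiA(N, -1e300), loB(N, 1e300), hiB(N, -1e300);
  const int nsrc = src_lin.size();

  for (int s = 0; s < nsteps; ++s) {
    double mx = 0.0;
    for (int kz = 1; kz < nz - 1; ++kz)
      for (int ky = 1; ky < ny - 1; ++ky) {
        const int o = kz * sz + ky * sy;
        for (int kx = 1; kx < nx - 1; ++kx) {
          const int k = o + kx;
          double L;
          if (uni[k]) {
            const double faces = pc[k + sx] + pc[k - sx] + pc[k + sy] +
                                 pc[k - sy] + pc[k + sz] + pc[k - sz];
            const double edges =
              pc[k + sx + sy] + pc[k + sx - sy] + pc[k - sx + sy] + pc[k - sx - sy] +
              pc[k + sx + sz] + pc[k + sx - sz] + pc[k - sx + sz] + pc[k - sx - sz] +
              pc[k + sy + sz] + pc[k + sy - sz] + pc[k - sy + sz] + pc[k - sy - sz];
            const double corners =
              pc[k + sx + sy + sz] + pc[k + sx + sy - sz] +
              pc[k + sx - sy + sz] + pc[k + sx - sy - sz] +
              pc[k - sx + sy + sz] + pc[k - sx + sy - sz] +
              pc[k - sx - sy + sz] + pc[k - sx - sy - sz];
            L = (wf * faces + we * edges + wc * corners - w0 * pc[k]) * invdx2;
          } else {
            const double re = rho_map[k] * c_map[k] / csim[k];
            L = ((0.5 + 0.5 * re * ir[k + sx]) * (pc[k + sx] - pc[k]) +
                 (0.5 + 0.5 * re * ir[k - sx]) * (pc[k - sx] - pc[k]) +
                 (0.5 + 0.5 * re * ir[k + sy]) * (pc[k + sy] - pc[k]) +
                 (0.5 + 0.5 * re * ir[k - sy]) * (pc[k - sy] - pc[k]) +
                 (0.5 + 0.5 * re * ir[k + sz]) * (pc[k + sz] - pc[k]) +
                 (0.5 + 0.5 * re * ir[k - sz]) * (pc[k - sz] - pc[k])) * invdx2;
          }
          lap[k] = L;
          double v = 2.0 * pc[k] - pm[k] + A[k] * L + B[k] * (L - lapprev[k]);
          if (C[k] != 0.0)
            v += C[k] * (pc[k] * pc[k] - 2.0 * pm[k] * pm[k] + pm2[k] * pm2[k]);
          pn[k] = flush(v);
        }
      }
    // Mur on the six faces
    auto mur = [&](int k, int kin) {
      const double m = (csim[k] * dt - dx) / (csim[k] * dt + dx);
      pn[k] = pc[kin] + m * (pn[kin] - pc[k]);
    };
    for (int kz = 0; kz < nz; ++kz)
      for (int ky = 0; ky < ny; ++ky) {
        mur(kz * sz + ky * sy, kz * sz + ky * sy + sx);
        mur(kz * sz + ky * sy + nx - 1, kz * sz + ky * sy + nx - 2);
      }
    for (int kz = 0; kz < nz; ++kz)
      for (int kx = 0; kx < nx; ++kx) {
        mur(kz * sz + kx, kz * sz + sy + kx);
        mur(kz * sz + (ny - 1) * sy + kx, kz * sz + (ny - 2) * sy + kx);
      }
    for (int ky = 0; ky < ny; ++ky)
      for (int kx = 0; kx < nx; ++kx) {
        mur(ky * sy + kx, sz + ky * sy + kx);
        mur((nz - 1) * sz + ky * sy + kx, (nz - 2) * sz + ky * sy + kx);
      }
    if (src_amp != 0.0) {
      const double t = omega * (s + 1) * dt;
      for (int q = 0; q < nsrc; ++q)
        pn[src_lin[q]] = src_amp * std::sin(t + src_phase[q]);
    }
    const bool inA = (s >= recA0 && s < recA1), inB = (s >= recB0 && s < recB1);
    for (int k = 0; k < N; ++k) {
      const double v = pn[k], a = std::fabs(v);
      if (a > mx) mx = a;
      if (inA) { if (v > hiA[k]) hiA[k] = v; if (v < loA[k]) loA[k] = v; }
      if (inB) { if (v > hiB[k]) hiB[k] = v; if (v < loB[k]) loB[k] = v; }
    }
    check_finite(mx, s);
    if (mx > blowup) stop("FDTD divergence: |p| exceeded %g at step %d", blowup, s);
    std::swap(lapprev, lap);
    pm2.swap(pm); pm.swap(pc); pc.swap(pn);
  }
  for (int k = 0; k < N; ++k) {
    ampA[k] = hiA[k] > loA[k] ? 0.5 * (hiA[k] - loA[k]) : 0.0;
    ampB[k] = hiB[k] > loB[k] ? 0.5 * (hiB[k] - loB[k]) : 0.0;
  }
  return List::create(_["ampA"] = ampA, _["ampB"] = ampB);
}
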