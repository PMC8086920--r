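// Pairwise-force core of the coupled SPH + lattice-spring tube model.
//
// Conventions:
//  - tube axis = x; the domain is periodic in x with period L (minimum image);
//    y and z are unbounded.
//  - phase 0 = membrane (lattice-spring solid), phase 1 = fluid (SPH).
//  - fluid-fluid pairs: Tait pressure + Monaghan-style artificial viscosity
//    with kernel-gradient weights; summation (default) or continuity density.
//  - membrane-fluid pairs: repulsive cosine coupling potential
//    U = A (1 + cos(pi r / r0)) for r < r0 (anti-compenetration).
//  - membrane-membrane: Hookean springs on an explicit bond list only.
//  - contraction: constant-magnitude force f pulling every membrane particle
//    whose wrapped axial coordinate falls in [x_wave, x_wave + dL) straight
//    toward the axis (no axial component).
//
// All pair forces are applied antisymmetrically, so with f = 0 total momentum
// is conserved to round-off regardless of the integrator.
//
// The integrator keeps type-split Verlet neighbour lists (fluid-fluid and
// membrane-fluid) built with a skin and rebuilt when the accumulated maximum
// displacement reaches half the skin.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

static inline double wrapx(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard the floor round-off edge
  if (x < 0) x = 0;
  return x;
}

static inline double minimg(double dx, double L) {
  if (dx > 0.5 * L) dx -= L;
  else if (dx < -0.5 * L) dx += L;
  return dx;
}

// kernel type: 0 = Lucy quartic, 1 = Wendland C2; support radius = h.
static inline double kern_dwdr(int type, double r, double h) {
  double q = r / h;
  if (q >= 1.0) return 0.0;
  double omq = 1.0 - q;
  if (type == 1) {
    // Wendland C2 (3D): W = 21/(2 pi h^3) (1-q)^4 (1+4q)
    return (21.0 / (2.0 * PI_ * h * h * h)) * (-20.0 * q * omq * omq * omq) / h;
  }
  // Lucy (3D): W = 105/(16 pi h^3) (1+3q)(1-q)^3
  return (105.0 / (16.0 * PI_ * h * h * h)) * (-12.0 * q * omq * omq) / h;
}

static inline double kern_w(int type, double r, double h) {
  double q = r / h;
  if (q >= 1.0) return 0.0;
  double omq = 1.0 - q;
  if (type == 1)
    return (21.0 / (2.0 * PI_ * h * h * h)) * omq * omq * omq * omq * (1.0 + 4.0 * q);
  return (105.0 / (16.0 * PI_ * h * h * h)) * (1.0 + 3.0 * q) * omq * omq * omq;
}

// [[Rcpp::export]]
double cpp_kernel_w(int type, double r, double h) { return kern_w(type, r, h); }

// Visit every unordered pair closer than cutoff (minimum image in x).
// Falls back to the O(N^2) loop when the box is too small for cells.
template <typename F>
static void for_each_pair(const double* px, const double* py, const double* pz,
                          int N, double cutoff, double L, F fn) {
  const double c2 = cutoff * cutoff;
  int nx = (int)std::floor(L / cutoff);
  if (nx < 3 || N < 96) {
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = minimg(px[i] - px[j], L);
        if (std::fabs(dx) >= cutoff) continue;
        double dy = py[i] - py[j];
        double dz = pz[i] - pz[j];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < c2) fn(i, j, r2);
      }
    }
    return;
  }
  double ymin = py[0], ymax = py[0], zmin = pz[0], zmax = pz[0];
  for (int i = 1; i < N; ++i) {
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
    if (pz[i] < zmin) zmin = pz[i];
    if (pz[i] > zmax) zmax = pz[i];
  }
  int ny = std::max(1, (int)std::floor((ymax - ymin) / cutoff));
  int nz = std::max(1, (int)std::floor((zmax - zmin) / cutoff));
  double cx = L / nx;
  double cy = (ymax - ymin) / ny;
  double cz = (zmax - zmin) / nz;
  if (cy <= 0) cy = 1.0;
  if (cz <= 0) cz = 1.0;
  int ncell = nx * ny * nz;
  std::vector<int> head(ncell, -1), next(N, -1);
  for (int i = 0; i < N; ++i) {
    int ix = (int)(wrapx(px[i], L) / cx); if (ix >= nx) ix = nx - 1;
    int iy = (int)((py[i] - ymin) / cy);  if (iy >= ny) iy = ny - 1;
    int iz = (int)((pz[i] - zmin) / cz);  if (iz >= nz) iz = nz - 1;
    int c = (iz * ny + iy) * nx + ix;
    next[i] = head[c];
    head[c] = i;
  }
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int ca = (iz * ny + iy) * nx + ix;
        if (head[ca] < 0) continue;
        for (int oz = -1; oz <= 1; ++oz) {
          int jz = iz + oz; if (jz < 0 || jz >= nz) continue;
          for (int oy = -1; oy <= 1; ++oy) {
            int jy = iy + oy; if (jy < 0 || jy >= ny) continue;
            for (int ox = -1; ox <= 1; ++ox) {
              int jx = ix + ox;
              if (jx < 0) jx += nx; else if (jx >= nx) jx -= nx;
              int cb = (jz * ny + jy) * nx + jx;
              if (cb < ca) continue;  // each unordered cell pair once
              for (int i = head[ca]; i >= 0; i = next[i]) {
                int jstart = (cb == ca) ? next[i] : head[cb];
                for (int j = jstart; j >= 0; j = next[j]) {
                  double dx = minimg(px[i] - px[j], L);
                  double dy = py[i] - py[j];
                  double dz = pz[i] - pz[j];
                  double r2 = dx * dx + dy * dy + dz * dz;
                  if (r2 < c2) fn(i, j, r2);
                }
              }
            }
          }
        }
      }
    }
  }
}

// All unordered pairs within cutoff (periodic in x); 1-based indices.
// Used by the spring builder and by brute-force oracles at larger N.
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pos, double cutoff, double L) {
  int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N);
  for (int i = 0; i < N; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::vector<int> ii, jj;
  for_each_pair(px.data(), py.data(), pz.data(), N, cutoff, L,
                [&](int i, int j, double) {
    ii.push_back(std::min(i, j) + 1); jj.push_back(std::max(i, j) + 1);
  });
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

struct Params {
  double m, k, rho0, c0, alpha, bvisc, h, A, r0c, f, dL, L;
  int kernel;
};

static Params read_params(const List& params) {
  Params p;
  p.m     = as<double>(params["m"]);
  p.k     = as<double>(params["k"]);
  p.rho0  = as<double>(params["rho0"]);
  p.c0    = as<double>(params["c0"]);
  p.alpha = as<double>(params["alpha"]);
  p.bvisc = as<double>(params["b"]);
  p.h     = as<double>(params["h"]);
  p.A     = as<double>(params["A"]);
  p.r0c   = as<double>(params["r0_couple"]);
  p.f     = as<double>(params["f"]);
  p.dL    = as<double>(params["dL"]);
  p.L     = as<double>(params["L"]);
  std::string kn = as<std::string>(params["kernel"]);
  p.kernel = (kn == "wendland") ? 1 : 0;
  return p;
}

// Fluid-fluid kernel sums (incl. self term): the raw summation density / m.
// [[Rcpp::export]]
NumericVector cpp_wsum(NumericMatrix pos, IntegerVector phase, List params) {
  int N = pos.nrow();
  Params p = read_params(params);
  std::vector<double> px(N), py(N), pz(N);
  for (int i = 0; i < N; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  NumericVector out(N);
  double w0 = p.m * kern_w(p.kernel, 0.0, p.h);
  for (int i = 0; i < N; ++i) out[i] = (phase[i] == 1) ? w0 : 0.0;
  for_each_pair(px.data(), py.data(), pz.data(), N, p.h, p.L,
                [&](int i, int j, double r2) {
    if (phase[i] == 1 && phase[j] == 1) {
      double w = p.m * kern_w(p.kernel, std::sqrt(r2), p.h);
      out[i] += w;
      out[j] += w;
    }
  });
  return out;
}

// type-split Verlet neighbour lists
struct NbrLists {
  std::vector<int> ffi, ffj;  // fluid-fluid, within h + skin
  std::vector<int> sfi, sfj;  // membrane-fluid, within r0c + skin
};

static void build_lists(const double* px, const double* py, const double* pz,
                        const int* phase, int N, const Params& p, double skin,
                        NbrLists& nl) {
  nl.ffi.clear(); nl.ffj.clear();
  nl.sfi.clear(); nl.sfj.clear();
  double cf = p.h + skin, cs = p.r0c + skin;
  double cf2 = cf * cf, cs2 = cs * cs;
  double cutoff = std::max(cf, cs);
  for_each_pair(px, py, pz, N, cutoff, p.L, [&](int i, int j, double r2) {
    int pi_ = phase[i], pj_ = phase[j];
    if (pi_ == 1 && pj_ == 1) {
      if (r2 < cf2) { nl.ffi.push_back(i); nl.ffj.push_back(j); }
    } else if (pi_ != pj_) {
      if (r2 < cs2) { nl.sfi.push_back(i); nl.sfj.push_back(j); }
    }
  });
}

// Pair forces + density rates + (optionally) kernel sums over the lists.
// Output arrays must be zeroed by the caller (wsum may be null).
static void eval_forces(const double* px, const double* py, const double* pz,
                        const double* vx, const double* vy, const double* vz,
                        const double* rho, const int* phase, int N,
                        const int* bi, const int* bj, const double* rest, int M,
                        const Params& p, double xwave, bool contract,
                        const NbrLists& nl,
                        double* fx, double* fy, double* fz, double* drho,
                        double* wsum) {
  // Tait pressure, zero at the reference density
  std::vector<double> P(N, 0.0);
  const double Bt = p.c0 * p.c0 * p.rho0 / 7.0;
  for (int i = 0; i < N; ++i) {
    if (phase[i] == 1) {
      double s = rho[i] / p.rho0;
      double s7 = s * s; s7 *= s7; s7 *= s7; s7 /= s;  // s^7
      P[i] = Bt * (s7 - 1.0);
    }
  }
  const double m = p.m, h = p.h, c0 = p.c0, alpha = p.alpha, bvisc = p.bvisc;
  const double h2 = h * h, r0c2 = p.r0c * p.r0c;
  const double Acoef = p.A * PI_ / p.r0c;
  for (size_t k = 0; k < nl.ffi.size(); ++k) {
    int i = nl.ffi[k], j = nl.ffj[k];
    double dx = minimg(px[i] - px[j], p.L);
    double dy = py[i] - py[j];
    double dz = pz[i] - pz[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= h2 || r2 <= 0) continue;
    double r = std::sqrt(r2);
    double dwdr = kern_dwdr(p.kernel, r, h);
    double gfac = dwdr / r;                       // grad_i W = gfac * r_ij
    double dvx = vx[i] - vx[j], dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
    double vdotr = dvx * dx + dvy * dy + dvz * dz;
    double Pi_ = alpha * h * c0 * (-vdotr) / ((rho[i] + rho[j]) * (r2 + bvisc * h2));
    double bracket = P[i] / (rho[i] * rho[i]) + P[j] / (rho[j] * rho[j]) + Pi_;
    double common = -m * m * bracket * gfac;
    fx[i] += common * dx; fy[i] += common * dy; fz[i] += common * dz;
    fx[j] -= common * dx; fy[j] -= common * dy; fz[j] -= common * dz;
    double dr = m * vdotr * gfac;
    drho[i] += dr;
    drho[j] += dr;
    if (wsum) {
      double w = m * kern_w(p.kernel, r, h);
      wsum[i] += w;
      wsum[j] += w;
    }
  }
  for (size_t k = 0; k < nl.sfi.size(); ++k) {
    int i = nl.sfi[k], j = nl.sfj[k];
    double dx = minimg(px[i] - px[j], p.L);
    double dy = py[i] - py[j];
    double dz = pz[i] - pz[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= r0c2 || r2 <= 0) continue;
    double r = std::sqrt(r2);
    double fmag = Acoef * std::sin(PI_ * r / p.r0c) / r;  // repulsive
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }
  // Hookean springs over the explicit bond list
  for (int b = 0; b < M; ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    double dx = minimg(px[i] - px[j], p.L);
    double dy = py[i] - py[j];
    double dz = pz[i] - pz[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) continue;
    double fmag = -p.k * (r - rest[b]) / r;  // attractive when stretched
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }
  // travelling contraction: radial pull toward the axis inside the window
  if (contract && p.f > 0) {
    for (int i = 0; i < N; ++i) {
      if (phase[i] != 0) continue;
      double d = wrapx(px[i] - xwave, p.L);
      if (d < p.dL) {
        double ryz = std::sqrt(py[i] * py[i] + pz[i] * pz[i]);
        if (ryz > 1e-12) {
          fy[i] -= p.f * py[i] / ryz;
          fz[i] -= p.f * pz[i] / ryz;
        }
      }
    }
  }
}

// Single force/density-rate evaluation (diagnostics and tests).
// [[Rcpp::export]]
List cpp_dmp_forces(NumericMatrix pos, NumericMatrix vel, NumericVector rho,
                    IntegerVector phase, IntegerMatrix bonds, NumericVector rest,
                    List params, double xwave, bool contract) {
  int N = pos.nrow(), M = bonds.nrow();
  Params p = read_params(params);
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
  }
  std::vector<int> bi(M), bj(M);
  std::vector<double> rs(M);
  for (int b = 0; b < M; ++b) { bi[b] = bonds(b,0); bj[b] = bonds(b,1); rs[b] = rest[b]; }
  NbrLists nl;
  build_lists(px.data(), py.data(), pz.data(), INTEGER(phase), N, p, 0.0, nl);
  std::vector<double> fx(N,0), fy(N,0), fz(N,0), drho(N,0);
  eval_forces(px.data(), py.data(), pz.data(), vx.data(), vy.data(), vz.data(),
              REAL(rho), INTEGER(phase), N, bi.data(), bj.data(), rs.data(), M,
              p, xwave, contract, nl,
              fx.data(), fy.data(), fz.data(), drho.data(), nullptr);
  NumericMatrix F(N, 3);
  NumericVector dr(N);
  for (int i = 0; i < N; ++i) { F(i,0)=fx[i]; F(i,1)=fy[i]; F(i,2)=fz[i]; dr[i]=drho[i]; }
  return List::create(_["force"] = F, _["drho"] = dr);
}

// Advance the coupled system nsteps velocity-Verlet steps of size dt.
// The contraction window origin moves with constant vwave during the chunk.
// density_mode 0: normalized summation density rho_i = rho0 wsum_i / wref_i
// (wref = each particle's kernel sum in the freshly built tube, so the
// initial state has rho = rho0 exactly and densities track the geometry);
// density_mode 1: continuity-equation integration.
// Returns the updated state plus a status code (0 ok, 1 density blow-up).
// [[Rcpp::export]]
List cpp_dmp_run(NumericMatrix pos, NumericMatrix vel, NumericVector rho,
                 NumericVector xun, IntegerVector phase,
                 IntegerMatrix bonds, NumericVector rest,
                 NumericVector wref, int density_mode,
                 List params, double dt, int nsteps,
                 double xwave, double vwave, bool contract,
                 double guard_lo, double guard_hi) {
  int N = pos.nrow(), M = bonds.nrow();
  Params p = read_params(params);
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N), rh(N), xu(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
    rh[i] = rho[i]; xu[i] = xun[i];
  }
  std::vector<int> bi(M), bj(M);
  std::vector<double> rs(M);
  for (int b = 0; b < M; ++b) { bi[b] = bonds(b,0); bj[b] = bonds(b,1); rs[b] = rest[b]; }
  std::vector<double> fx(N,0), fy(N,0), fz(N,0), drho(N,0), ws(N,0);
  const bool summation = (density_mode == 0);
  const double minv = 1.0 / p.m;
  const double rho_lo = guard_lo * p.rho0, rho_hi = guard_hi * p.rho0;
  const double wself = p.m * kern_w(p.kernel, 0.0, p.h);
  const double skin = 0.25 * std::max(p.h, p.r0c);
  int status = 0, bad_step = -1, bad_particle = -1;

  NbrLists nl;
  build_lists(px.data(), py.data(), pz.data(), INTEGER(phase), N, p, skin, nl);
  double travel = 0.0;  // accumulated max displacement since last rebuild

  eval_forces(px.data(), py.data(), pz.data(), vx.data(), vy.data(), vz.data(),
              rh.data(), INTEGER(phase), N, bi.data(), bj.data(), rs.data(), M,
              p, xwave, contract, nl,
              fx.data(), fy.data(), fz.data(), drho.data(), nullptr);
  for (int step = 0; step < nsteps; ++step) {
    double hdt = 0.5 * dt * minv;
    double vmax2 = 0.0;
    for (int i = 0; i < N; ++i) {
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
      double v2 = vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i];
      if (v2 > vmax2) vmax2 = v2;
      px[i] = wrapx(px[i] + dt * vx[i], p.L);
      py[i] += dt * vy[i];
      pz[i] += dt * vz[i];
      xu[i] += dt * vx[i];
    }
    xwave = wrapx(xwave + vwave * dt, p.L);
    travel += std::sqrt(vmax2) * dt;
    if (2.0 * travel >= skin) {
      build_lists(px.data(), py.data(), pz.data(), INTEGER(phase), N, p, skin, nl);
      travel = 0.0;
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(drho.begin(), drho.end(), 0.0);
    if (summation) std::fill(ws.begin(), ws.end(), 0.0);
    eval_forces(px.data(), py.data(), pz.data(), vx.data(), vy.data(), vz.data(),
                rh.data(), INTEGER(phase), N, bi.data(), bj.data(), rs.data(), M,
                p, xwave, contract, nl,
                fx.data(), fy.data(), fz.data(), drho.data(),
                summation ? ws.data() : nullptr);
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      if (phase[i] == 1) {
        if (summation) {
          // forces above used the half-step-lagged density; update now
          rh[i] = p.rho0 * (ws[i] + wself) / wref[i];
        } else {
          rh[i] += dt * drho[i];
        }
        if (!(rh[i] > rho_lo && rh[i] < rho_hi)) {
          bad = true;
          if (bad_particle < 0) { bad_particle = i + 1; bad_step = step + 1; }
        }
      }
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
    }
    if (bad) { status = 1; break; }
  }

  NumericMatrix opos(N,3), ovel(N,3);
  NumericVector orho(N), oxun(N);
  for (int i = 0; i < N; ++i) {
    opos(i,0)=px[i]; opos(i,1)=py[i]; opos(i,2)=pz[i];
    ovel(i,0)=vx[i]; ovel(i,1)=vy[i]; ovel(i,2)=vz[i];
    orho[i]=rh[i]; oxun[i]=xu[i];
  }
  return List::create(_["pos"] = opos, _["vel"] = ovel, _["rho"] = orho,
                      _["xun"] = oxun, _["x_wave"] = xwave,
                      _["status"] = status, _["bad_step"] = bad_step,
                      _["bad_particle"] = bad_particle);
}
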