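// Lattice Boltzmann BGK solver (D2Q9 / D3Q19) for quasi-static incompressible
// flow on the shared voxel lattice. Full-way bounce-back on wall and bound-
// platelet nodes; prescribed-profile equilibrium inlet; zero-gradient outlet.
// Lattice units: dx_l = spacing, dt chosen from tau and the physical kinematic
// viscosity, nu_l = (tau - 0.5)/3.
#include <Rcpp.h>
#include "ftz.h"
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Lattice {
  int q;
  const int (*c)[3];
  const double *w;
  const int *opp;
};

static const int C2[9][3] = {{0,0,0},{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},
                             {1,1,0},{-1,-1,0},{1,-1,0},{-1,1,0}};
static const double W2[9] = {4.0/9,1.0/9,1.0/9,1.0/9,1.0/9,
                             1.0/36,1.0/36,1.0/36,1.0/36};
static const int O2[9] = {0,2,1,4,3,6,5,8,7};

static const int C3[19][3] = {
  {0,0,0},
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{-1,-1,0},{1,-1,0},{-1,1,0},
  {1,0,1},{-1,0,-1},{1,0,-1},{-1,0,1},
  {0,1,1},{0,-1,-1},{0,1,-1},{0,-1,1}};
static const double W3[19] = {
  1.0/3,
  1.0/18,1.0/18,1.0/18,1.0/18,1.0/18,1.0/18,
  1.0/36,1.0/36,1.0/36,1.0/36,
  1.0/36,1.0/36,1.0/36,1.0/36,
  1.0/36,1.0/36,1.0/36,1.0/36};
static const int O3[19] = {0,2,1,4,3,6,5,8,7,10,9,12,11,14,13,16,15,18,17};

Lattice get_lattice(int ndim) {
  if (ndim == 2) return {9, C2, W2, O2};
  return {19, C3, W3, O3};
}

inline double feq(const Lattice &L, int i, double rho,
                  double ux, double uy, double uz) {
  double cu = L.c[i][0]*ux + L.c[i][1]*uy + L.c[i][2]*uz;
  double u2 = ux*ux + uy*uy + uz*uz;
  return L.w[i] * rho * (1.0 + 3.0*cu + 4.5*cu*cu - 1.5*u2);
}

} // namespace

// flags_eff: 0 fluid, 1 solid (wall/collagen/bound platelet), 2 inlet, 3 outlet
// inlet_ux_l: per-node axial inlet velocity in lattice units (nonzero at inlet)
// f_init: length n*q or 0 (cold start from inlet-profile-free equilibrium)
// [[Rcpp::export]]
List lb_solve_cpp(IntegerVector flags_eff, IntegerVector dims, int ndim,
                  NumericVector inlet_ux_l, double tau,
                  NumericVector f_init, int max_iter, int check_every,
                  double tol) {
  FtzGuard ftz_guard;
  const Lattice L = get_lattice(ndim);
  const int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  const int n = nx * ny * nz;
  const int q = L.q;

  std::vector<double> f(n * q), f2(n * q);
  if (f_init.size() == (R_xlen_t)n * q) {
    std::copy(f_init.begin(), f_init.end(), f.begin());
  } else {
    for (int k = 0; k < n; ++k)
      for (int i = 0; i < q; ++i) f[(size_t)k*q + i] = L.w[i];
  }

  // precompute pull neighbors: nb[k*q+i] = index streamed from, -1 = bounce
  std::vector<int> nb((size_t)n * q, -1);
  std::vector<signed char> fl(n);
  for (int k = 0; k < n; ++k) fl[k] = (signed char)flags_eff[k];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int k = x + nx*(y + ny*z);
        if (fl[k] == 1) continue;
        for (int i = 0; i < q; ++i) {
          int xs = x - L.c[i][0], ys = y - L.c[i][1], zs = z - L.c[i][2];
          if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs < 0 || zs >= nz)
            continue;                       // stays -1: bounce-back from border
          int ks = xs + nx*(ys + ny*zs);
          if (fl[ks] == 1) continue;        // solid neighbor: bounce-back
          nb[(size_t)k*q + i] = ks;
        }
      }

  std::vector<double> ux(n, 0.0), uy(n, 0.0), uz(n, 0.0), rho(n, 1.0);
  std::vector<double> uxp(n, 0.0), uyp(n, 0.0), uzp(n, 0.0);
  std::vector<double> resid;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // collision (in place); open boundaries use non-equilibrium extrapolation
    // (Guo): f = feq(imposed moments) + fneq of the adjacent interior node.
    // Inlet imposes the velocity profile with the neighbor's density; outlet
    // imposes the reference density with the neighbor's velocity.
    for (int k = 0; k < n; ++k) {
      if (fl[k] == 1) continue;
      double *fk = &f[(size_t)k*q];
      if (fl[k] == 2 || fl[k] == 3) {
        int x = k % nx;
        int knb = (fl[k] == 2) ? k + 1 : k - 1;
        if (x + ((fl[k] == 2) ? 1 : -1) < 0 || fl[knb] == 1) {
          for (int i = 0; i < q; ++i)
            fk[i] = feq(L, i, 1.0, inlet_ux_l[k], 0.0, 0.0);
          continue;
        }
        const double *fn = &f[(size_t)knb*q];
        double rn = 0, vx = 0, vy = 0, vz = 0;
        for (int i = 0; i < q; ++i) {
          rn += fn[i];
          vx += fn[i]*L.c[i][0]; vy += fn[i]*L.c[i][1]; vz += fn[i]*L.c[i][2];
        }
        vx /= rn; vy /= rn; vz /= rn;
        double rb, bx, by, bz;
        if (fl[k] == 2) { rb = rn; bx = inlet_ux_l[k]; by = 0; bz = 0; }
        else           { rb = 1.0; bx = vx; by = vy; bz = vz; }
        rho[k] = rb; ux[k] = bx; uy[k] = by; uz[k] = bz;
        for (int i = 0; i < q; ++i) {
          double fneq = fn[i] - feq(L, i, rn, vx, vy, vz);
          fk[i] = feq(L, i, rb, bx, by, bz) + (1.0 - 1.0/tau) * fneq;
        }
        continue;
      }
      double r = 0, vx = 0, vy = 0, vz = 0;
      for (int i = 0; i < q; ++i) {
        r += fk[i];
        vx += fk[i]*L.c[i][0]; vy += fk[i]*L.c[i][1]; vz += fk[i]*L.c[i][2];
      }
      vx /= r; vy /= r; vz /= r;
      rho[k] = r; ux[k] = vx; uy[k] = vy; uz[k] = vz;
      for (int i = 0; i < q; ++i)
        fk[i] += (feq(L, i, r, vx, vy, vz) - fk[i]) / tau;
    }
    // streaming (pull) with bounce-back
    for (int k = 0; k < n; ++k) {
      if (fl[k] == 1) continue;
      double *gk = &f2[(size_t)k*q];
      const double *fk = &f[(size_t)k*q];
      const int *nbk = &nb[(size_t)k*q];
      for (int i = 0; i < q; ++i)
        gk[i] = (nbk[i] >= 0) ? f[(size_t)nbk[i]*q + i] : fk[L.opp[i]];
    }
    f.swap(f2);

    if (iter % check_every == 0) {
      double num = 0, den = 0;
      for (int k = 0; k < n; ++k) {
        if (fl[k] == 1) continue;
        double dx_ = ux[k]-uxp[k], dy_ = uy[k]-uyp[k], dz_ = uz[k]-uzp[k];
        num += dx_*dx_ + dy_*dy_ + dz_*dz_;
        den += ux[k]*ux[k] + uy[k]*uy[k] + uz[k]*uz[k];
      }
      double r = (den > 0) ? std::sqrt(num/den) : std::sqrt(num);
      resid.push_back(r);
      uxp = ux; uyp = uy; uzp = uz;
      if (r < tol && iter > check_every) { converged = true; break; }
    }
  }

  // final macroscopic moments and shear rate from non-equilibrium populations:
  // S_ab = -3/(2 rho tau) * sum_i f_i^neq c_ia c_ib (per lattice time step);
  // gamma_l = sqrt(2 S:S)
  NumericVector outux(n), outuy(n), outuz(n), outrho(n), gam(n);
  for (int k = 0; k < n; ++k) {
    if (fl[k] == 1) { outrho[k] = 1.0; continue; }
    if (fl[k] == 2 || fl[k] == 3) {
      // boundary nodes carry the moments imposed at the last collision
      outrho[k] = rho[k]; outux[k] = ux[k]; outuy[k] = uy[k]; outuz[k] = uz[k];
      continue;
    }
    const double *fk = &f[(size_t)k*q];
    double r = 0, vx = 0, vy = 0, vz = 0;
    for (int i = 0; i < q; ++i) {
      r += fk[i];
      vx += fk[i]*L.c[i][0]; vy += fk[i]*L.c[i][1]; vz += fk[i]*L.c[i][2];
    }
    vx /= r; vy /= r; vz /= r;
    outrho[k] = r; outux[k] = vx; outuy[k] = vy; outuz[k] = vz;
    double S[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int i = 0; i < q; ++i) {
      double fneq = fk[i] - feq(L, i, r, vx, vy, vz);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          S[a][b] += fneq * L.c[i][a] * L.c[i][b];
    }
    double ss = 0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double s = -1.5 / (r * tau) * S[a][b];
        ss += s * s;
      }
    gam[k] = std::sqrt(2.0 * ss);
  }
  // boundary columns inherit the adjacent interior shear rate
  for (int k = 0; k < n; ++k) {
    if (fl[k] == 2 && fl[k + 1] != 1) gam[k] = gam[k + 1];
    else if (fl[k] == 3 && fl[k - 1] != 1) gam[k] = gam[k - 1];
  }

  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["ux"] = outux, _["uy"] = outuy, _["uz"] = outuz,
                      _["rho"] = outrho, _["gamma_l"] = gam,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["residuals"] = NumericVector(resid.begin(), resid.end()));
}

// equilibrium populations for one node (lattice units); used to re-initialize
// nodes freed by platelet detachment
// [[Rcpp::export]]
NumericVector lb_equilibrium_cpp(int ndim, double rho, NumericVector u_l) {
  const Lattice L = get_lattice(ndim);
  NumericVector out(L.q);
  double ux = u_l[0], uy = u_l.size() > 1 ? u_l[1] : 0.0,
         uz = u_l.size() > 2 ? u_l[2] : 0.0;
  for (int i = 0; i < L.q; ++i) out[i] = feq(L, i, rho, ux, uy, uz);
  return out;
}
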