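// Rejection-free lattice kinetic Monte Carlo engine for platelet motion,
// adhesion and detachment. A rate database over all platelets (hops along
// each axis, attach, detach) is kept in a Fenwick tree for O(log N) event
// selection and local O(1) updates after each executed event; scheduled
// inlet arrivals are merged into the event clock. All randomness comes from
// R's RNG (unif_rand), so runs are bit-reproducible under set.seed().
//
// Units: dx in mm, velocity mm/s, shear 1/s, diffusivity mm^2/s, rates 1/s.
// Node flags: 0 fluid, 1 wall, 2 inlet, 3 outlet, 4 collagen.
// Platelet state: 0 mobile, 1 bound; pnode = -1 before entry / after exit.
#include <Rcpp.h>
#include "ftz.h"
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Fenwick {
  std::vector<double> tree;
  int n;
  void init(int n_) { n = n_; tree.assign(n + 1, 0.0); }
  void add(int i, double delta) {
    for (++i; i <= n; i += i & (-i)) tree[i] += delta;
  }
  double total() const {
    double s = 0;
    for (int i = n; i > 0; i -= i & (-i)) s += tree[i];
    return s;
  }
  // smallest index with prefix sum > target
  int search(double target) const {
    int pos = 0;
    int log = 1;
    while ((1 << log) <= n) ++log;
    for (int k = log; k >= 0; --k) {
      int next = pos + (1 << k);
      if (next <= n && tree[next] < target) {
        pos = next;
        target -= tree[next];
      }
    }
    return pos; // 0-based platelet index
  }
};

struct Params {
  double D_p, k_att0, k_att0_col, k_det0, k_det0_col;
  double gamma_c, W_max, gamma_vwf, s_vwf;
};

inline double vwf_W(double g, const Params &P) {
  // baseline-normalized logistic: exactly 1 at zero shear, W_max at high
  double s0 = 1.0 / (1.0 + std::exp(P.gamma_vwf / P.s_vwf));
  double s = 1.0 / (1.0 + std::exp(-(g - P.gamma_vwf) / P.s_vwf));
  double f = (s - s0) / (1.0 - s0);
  if (f < 0) f = 0;
  return 1.0 + (P.W_max - 1.0) * f;
}

} // namespace

// [[Rcpp::export]]
List lkmc_run_cpp(IntegerVector flags, IntegerVector dims, int ndim,
                  double dx, NumericMatrix vel, NumericVector gamma,
                  IntegerVector pnode_in, IntegerVector pstate_in,
                  NumericVector pF, LogicalVector pcol_in,
                  NumericVector arr_time, IntegerVector arr_node,
                  IntegerVector arr_slot,
                  double t0, double t1, List params_, bool log_events) {
  FtzGuard ftz_guard;
  const int nx = dims[0], ny = dims[1], nz = (ndim == 3) ? dims[2] : 1;
  const int nnode = nx * ny * nz;
  const int np = pnode_in.size();
  Params P;
  P.D_p = params_["D_p_mm2s"]; P.k_att0 = params_["k_att0"];
  P.k_att0_col = params_["k_att0_col"]; P.k_det0 = params_["k_det0"];
  P.k_det0_col = params_["k_det0_col"]; P.gamma_c = params_["gamma_c"];
  P.W_max = params_["W_max"]; P.gamma_vwf = params_["gamma_vwf"];
  P.s_vwf = params_["s_vwf"];
  const double Ddx2 = P.D_p / (dx * dx);

  // axis strides and direction list (+axis, -axis per dimension)
  int stride[3] = {1, nx, nx * ny};
  int ndir = 2 * ndim;

  std::vector<int> pnode(pnode_in.begin(), pnode_in.end());
  std::vector<int> pstate(pstate_in.begin(), pstate_in.end());
  std::vector<int> pcol(np);
  for (int i = 0; i < np; ++i) pcol[i] = pcol_in[i] ? 1 : 0;

  // node -> platelet occupancy (-1 free)
  std::vector<int> occ(nnode, -1);
  for (int i = 0; i < np; ++i)
    if (pnode[i] >= 0) occ[pnode[i]] = i;

  // coordinates from linear index
  auto coord = [&](int k, int a) {
    if (a == 0) return k % nx;
    if (a == 1) return (k / nx) % ny;
    return k / (nx * ny);
  };
  auto open_node = [&](int k) {
    int f = flags[k];
    return f == 0 || f == 3; // fluid or outlet; inlet/wall/collagen block
  };

  // per-platelet event rates: ndir hops, then attach, then detach
  std::vector<double> rates((size_t)np * (ndir + 2), 0.0);
  std::vector<double> ptot(np, 0.0);
  Fenwick fw;
  fw.init(np);

  // recompute all rates of platelet i and push the new total into the tree
  auto recompute = [&](int i) {
    double *r = &rates[(size_t)i * (ndir + 2)];
    for (int e = 0; e < ndir + 2; ++e) r[e] = 0.0;
    double tot = 0.0;
    int k = pnode[i];
    if (k >= 0 && pstate[i] == 0) {       // mobile: hops + attach
      for (int a = 0; a < ndim; ++a) {
        int c = coord(k, a);
        int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
        double u = vel(k, a);
        // +axis
        double rp = Ddx2 + (u > 0 ? u / dx : 0.0);
        if (c + 1 >= lim) {
          if (a != 0) rp = 0.0;            // only +x leads out (exit)
        } else {
          int kn = k + stride[a];
          if (!open_node(kn) || occ[kn] >= 0) rp = 0.0;
        }
        // -axis
        double rm = Ddx2 + (u < 0 ? -u / dx : 0.0);
        if (c - 1 < 0) rm = 0.0;
        else {
          int kn = k - stride[a];
          if (!open_node(kn) || occ[kn] >= 0) rm = 0.0;
        }
        r[2 * a] = rp; r[2 * a + 1] = rm;
        tot += rp + rm;
      }
      // attach: adjacent to collagen or a bound platelet
      bool near_col = false;
      double f_sub = -1.0;
      for (int a = 0; a < ndim; ++a) {
        int c = coord(k, a);
        int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
        if (c + 1 < lim) {
          int kn = k + stride[a];
          if (flags[kn] == 4) near_col = true;
          else if (occ[kn] >= 0 && pstate[occ[kn]] == 1)
            f_sub = std::max(f_sub, pF[occ[kn]]);
        }
        if (c - 1 >= 0) {
          int kn = k - stride[a];
          if (flags[kn] == 4) near_col = true;
          else if (occ[kn] >= 0 && pstate[occ[kn]] == 1)
            f_sub = std::max(f_sub, pF[occ[kn]]);
        }
      }
      double W = vwf_W(gamma[k], P);
      double ra = 0.0;
      if (near_col) ra = P.k_att0_col * pF[i] * W;
      if (f_sub > 0) {
        double rp2 = P.k_att0 * std::max(pF[i], f_sub) * W;
        ra = std::max(ra, rp2);
      }
      r[ndir] = ra;
      tot += ra;
    } else if (k >= 0 && pstate[i] == 1) { // bound: detach only
      // the shear load on a bound platelet is the surface traction: take
      // the largest shear rate over adjacent open (fluid) nodes - the
      // platelet's own node is a no-slip solid with vanishing local shear
      double gsurf = 0.0;
      for (int a = 0; a < ndim; ++a) {
        int c = coord(k, a);
        int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
        if (c + 1 < lim) {
          int kn = k + stride[a];
          if (open_node(kn) && occ[kn] < 0 && gamma[kn] > gsurf)
            gsurf = gamma[kn];
        }
        if (c - 1 >= 0) {
          int kn = k - stride[a];
          if (open_node(kn) && occ[kn] < 0 && gamma[kn] > gsurf)
            gsurf = gamma[kn];
        }
      }
      double k0 = pcol[i] ? P.k_det0_col : P.k_det0;
      // saturate the slip-bond exponent: beyond ~8 shear scales the bond
      // is gone either way, and unbounded rates would freeze the clock
      double ex = gsurf / P.gamma_c;
      if (ex > 8.0) ex = 8.0;
      // vWF stabilization: elongated vWF multiplies capture AND resists
      // shear-driven bond rupture across the same conformational switch
      double rd = k0 * (1.0 / pF[i]) * std::exp(ex) / vwf_W(gsurf, P);
      r[ndir + 1] = rd;
      tot += rd;
    }
    fw.add(i, tot - ptot[i]);
    ptot[i] = tot;
  };

  // platelets adjacent to node k (by occupancy)
  auto neighbors_of = [&](int k, std::vector<int> &out) {
    for (int a = 0; a < ndim; ++a) {
      int c = coord(k, a);
      int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
      if (c + 1 < lim && occ[k + stride[a]] >= 0)
        out.push_back(occ[k + stride[a]]);
      if (c - 1 >= 0 && occ[k - stride[a]] >= 0)
        out.push_back(occ[k - stride[a]]);
    }
  };
  auto has_support = [&](int i) {
    int k = pnode[i];
    for (int a = 0; a < ndim; ++a) {
      int c = coord(k, a);
      int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
      if (c + 1 < lim) {
        int kn = k + stride[a];
        if (flags[kn] == 4) return true;
        if (occ[kn] >= 0 && pstate[occ[kn]] == 1 && occ[kn] != i) return true;
      }
      if (c - 1 >= 0) {
        int kn = k - stride[a];
        if (flags[kn] == 4) return true;
        if (occ[kn] >= 0 && pstate[occ[kn]] == 1 && occ[kn] != i) return true;
      }
    }
    return false;
  };
  auto touches_collagen = [&](int k) {
    for (int a = 0; a < ndim; ++a) {
      int c = coord(k, a);
      int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
      if (c + 1 < lim && flags[k + stride[a]] == 4) return true;
      if (c - 1 >= 0 && flags[k - stride[a]] == 4) return true;
    }
    return false;
  };

  for (int i = 0; i < np; ++i) recompute(i);

  // event log
  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_p, ev_node; // 1 ins, 2 att, 3 det, 4 exit
  auto log_ev = [&](double t, int type, int p, int node) {
    if (!log_events) return;
    if (ev_t.size() > 5000000)
      Rcpp::stop("event storm: > 5e6 logged events in one horizon");
    ev_t.push_back(t); ev_type.push_back(type);
    ev_p.push_back(p); ev_node.push_back(node);
  };

  RNGScope scope;
  double t = t0;
  int i_arr = 0;
  const int n_arr = arr_time.size();
  int n_new_bound = 0, n_dropped = 0;
  long n_events = 0;
  std::vector<int> nb;
  nb.reserve(16);

  while (t < t1) {
    double R = fw.total();
    double t_next = R > 0 ? t - std::log(unif_rand()) / R : R_PosInf;
    double t_arrival = (i_arr < n_arr) ? arr_time[i_arr] : R_PosInf;

    if (t_arrival <= t_next && t_arrival <= t1) {
      // scheduled insertion: place at the sampled inlet node, sliding along
      // the cross-section if occupied; drop if no free node nearby
      t = t_arrival;
      int slot = arr_slot[i_arr] - 1;     // R 1-based
      int k = arr_node[i_arr] - 1;
      ++i_arr;
      int placed = -1;
      if (occ[k] < 0 && open_node(k)) placed = k;
      else {
        for (int s = 1; s <= 3 && placed < 0; ++s) {
          for (int sgn = -1; sgn <= 1 && placed < 0; sgn += 2) {
            int c = coord(k, 1) + sgn * s;
            if (c < 0 || c >= ny) continue;
            int kn = k + sgn * s * stride[1];
            if (occ[kn] < 0 && open_node(kn)) placed = kn;
          }
        }
      }
      if (placed >= 0) {
        pnode[slot] = placed;
        pstate[slot] = 0;
        occ[placed] = slot;
        recompute(slot);
        nb.clear(); neighbors_of(placed, nb);
        for (int j : nb) if (j != slot) recompute(j);
        log_ev(t, 1, slot, placed);
      } else {
        ++n_dropped;
      }
      continue;
    }
    if (t_next > t1 || !R_FINITE(t_next)) break;
    t = t_next;
    ++n_events;

    // select platelet, then event within platelet
    double u = unif_rand() * R;
    int i = fw.search(u);
    if (i >= np) i = np - 1;
    // floating-point edge: the draw can land on a rate-free slot when u
    // is within rounding of the cached total; treat as a no-op tick
    if (ptot[i] <= 0.0 || pnode[i] < 0) continue;
    double *r = &rates[(size_t)i * (ndir + 2)];
    double acc = 0, pick = unif_rand() * ptot[i];
    int e = -1;
    for (int q = 0; q < ndir + 2; ++q) {
      acc += r[q];
      if (r[q] > 0 && pick <= acc) { e = q; break; }
    }
    if (e < 0) {
      for (int q = ndir + 1; q >= 0; --q) if (r[q] > 0) { e = q; break; }
    }
    if (e < 0) continue;

    if (e < ndir) {                        // hop
      int a = e / 2, sgn = (e % 2 == 0) ? 1 : -1;
      int k = pnode[i];
      int c = coord(k, a);
      int lim = (a == 0) ? nx : (a == 1 ? ny : nz);
      if (a == 0 && sgn > 0 && c + 1 >= lim) {
        // exit through the outlet face
        occ[k] = -1;
        pnode[i] = -1;
        recompute(i);
        nb.clear(); neighbors_of(k, nb);
        for (int j : nb) recompute(j);
        log_ev(t, 4, i, k);
        continue;
      }
      int kn = k + sgn * stride[a];
      occ[k] = -1;
      occ[kn] = i;
      pnode[i] = kn;
      recompute(i);
      nb.clear();
      neighbors_of(k, nb); neighbors_of(kn, nb);
      for (int j : nb) if (j != i) recompute(j);
    } else if (e == ndir) {                // attach
      pstate[i] = 1;
      pcol[i] = touches_collagen(pnode[i]) ? 1 : 0;
      ++n_new_bound;
      recompute(i);
      nb.clear(); neighbors_of(pnode[i], nb);
      for (int j : nb) if (j != i) recompute(j);
      log_ev(t, 2, i, pnode[i]);
    } else {                               // detach
      pstate[i] = 0;
      pcol[i] = 0;
      recompute(i);
      log_ev(t, 3, i, pnode[i]);
      // support cascade: bound neighbors losing their last anchor go mobile
      std::queue<int> qq;
      nb.clear(); neighbors_of(pnode[i], nb);
      for (int j : nb) if (pstate[j] == 1) qq.push(j);
      while (!qq.empty()) {
        int j = qq.front(); qq.pop();
        if (pstate[j] != 1 || has_support(j)) continue;
        pstate[j] = 0;
        pcol[j] = 0;
        recompute(j);
        log_ev(t, 3, j, pnode[j]);
        std::vector<int> nb2;
        neighbors_of(pnode[j], nb2);
        for (int j2 : nb2) if (pstate[j2] == 1) qq.push(j2);
      }
      nb.clear(); neighbors_of(pnode[i], nb);
      for (int j : nb) if (j != i) recompute(j);
    }
  }

  return List::create(
    _["pnode"] = IntegerVector(pnode.begin(), pnode.end()),
    _["pstate"] = IntegerVector(pstate.begin(), pstate.end()),
    _["pcol"] = LogicalVector(pcol.begin(), pcol.end()),
    _["n_new_bound"] = n_new_bound,
    _["n_dropped"] = n_dropped,
    _["n_events"] = (double)n_events,
    _["ev_time"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["ev_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
    _["ev_platelet"] = IntegerVector(ev_p.begin(), ev_p.end()),
    _["ev_node"] = IntegerVector(ev_node.begin(), ev_node.end()),
    _["t_end"] = std::min(t, t1));
}
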