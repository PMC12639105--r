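// Coarse-grained force field and Langevin (BAOAB) integrator.
//
// Units are reduced: length in bead diameters (1 lu ~ 5 Angstrom), energy in
// kBT at 300 K, friction and timestep as dimensionless Langevin parameters.
// The ring body, pore lining, nucleosome core and histone-surface patch beads
// are frozen interaction sources; DNA, pore loops and factor beads are mobile.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>

// fast deterministic exp: range reduction x = k ln2 + r with |r| <= ln2/2,
// 2^k assembled from bits, exp(r) by Taylor series to double accuracy
// (~1e-15 relative; this toolchain's libm exp is several times slower)
static inline double fexp(double x) {
  if (x < -708.0) return 0.0;
  if (x > 708.0) return std::exp(x);
  double k = std::nearbyint(x * 1.4426950408889634);
  double r = x - k * 0.6931471805599453;
  // Taylor of exp(r), |r| <= 0.3466
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0/6 + r * (1.0/24 +
             r * (1.0/120 + r * (1.0/720 + r * (1.0/5040 + r * (1.0/40320 +
             r * (1.0/362880 + r * (1.0/3628800 + r * 1.0/39916800))))))))));
  int64_t ki = (int64_t)k;
  union { uint64_t u; double d; } two_k;
  two_k.u = (uint64_t)(ki + 1023) << 52;
  return p * two_k.d;
}

using namespace Rcpp;

namespace {

struct Topology {
  int n;
  std::vector<double> radius, mass, ev_eps, qd, qp; // qd: intra-DNA charge, qp: protein-DNA charge
  std::vector<int> is_dna, mobile;
  // bonded terms
  std::vector<int> bond_i, bond_j;        std::vector<double> bond_r0, bond_k;
  std::vector<int> ang_i, ang_j, ang_k;   std::vector<double> ang_t0, ang_kk;
  // Morse pairs (base pairing) and stacking
  std::vector<int> mor_i, mor_j;          std::vector<double> mor_eps, mor_alpha, mor_r0;
  std::vector<int> stk_i, stk_j;          std::vector<double> stk_eps, stk_alpha, stk_r0;
  // always-on Gaussian site wells (nucleosome sites, RPA, FACT tail)
  std::vector<int> site_i, site_j;        std::vector<double> site_eps, site_sig, site_r0;
  // position restraints (weak COM anchor on distal termini)
  std::vector<int> pr_i;                  std::vector<double> pr_x, pr_y, pr_z, pr_k;
  // nonbonded parameters
  double eps_ev, lB, kappa, r_cut_dh;
  // exclusions as per-bead adjacency (small, sorted)
  std::vector<std::vector<int>> excl_adj;
  // state-dependent terms
  std::vector<int> well_loop, well_mate;  std::vector<double> well_eps, well_sig, well_r0, well_brk;
  double well_ramp = 1.0;  // ramp length (steps) after the delay
  double well_delay = 0.0; // contacts stay off this long after engaging
  double well_refract_steps = 0.0; // release duration after a forced break
  std::vector<int> eligible;              // phosphate beads of the tracked strand
  std::vector<int> nat_i, nat_j;          std::vector<double> nat_r0, nat_k;
  // state-dependent loop position restraints (capped harmonic to target)
  std::vector<int> lpr_i;                 std::vector<double> lpr_x, lpr_y, lpr_z, lpr_k;
  double nat_dcap = 0.5;
};

inline bool excluded(const Topology& T, int i, int j) {
  const std::vector<int>& a = T.excl_adj[i];
  for (size_t k = 0; k < a.size(); ++k) if (a[k] == j) return true;
  return false;
}

void read_term_matrices(const List& tl, Topology& T) {
  IntegerMatrix b = tl["bonds_ij"]; NumericMatrix bp = tl["bonds_par"];
  for (int r = 0; r < b.nrow(); ++r) {
    T.bond_i.push_back(b(r,0)); T.bond_j.push_back(b(r,1));
    T.bond_r0.push_back(bp(r,0)); T.bond_k.push_back(bp(r,1));
  }
  IntegerMatrix a = tl["angles_ijk"]; NumericMatrix ap = tl["angles_par"];
  for (int r = 0; r < a.nrow(); ++r) {
    T.ang_i.push_back(a(r,0)); T.ang_j.push_back(a(r,1)); T.ang_k.push_back(a(r,2));
    T.ang_t0.push_back(ap(r,0)); T.ang_kk.push_back(ap(r,1));
  }
  IntegerMatrix m = tl["morse_ij"]; NumericMatrix mp = tl["morse_par"];
  for (int r = 0; r < m.nrow(); ++r) {
    T.mor_i.push_back(m(r,0)); T.mor_j.push_back(m(r,1));
    T.mor_eps.push_back(mp(r,0)); T.mor_alpha.push_back(mp(r,1)); T.mor_r0.push_back(mp(r,2));
  }
  IntegerMatrix s = tl["stack_ij"]; NumericMatrix sp = tl["stack_par"];
  for (int r = 0; r < s.nrow(); ++r) {
    T.stk_i.push_back(s(r,0)); T.stk_j.push_back(s(r,1));
    T.stk_eps.push_back(sp(r,0)); T.stk_alpha.push_back(sp(r,1)); T.stk_r0.push_back(sp(r,2));
  }
  IntegerMatrix w = tl["site_ij"]; NumericMatrix wp = tl["site_par"];
  for (int r = 0; r < w.nrow(); ++r) {
    T.site_i.push_back(w(r,0)); T.site_j.push_back(w(r,1));
    T.site_eps.push_back(wp(r,0)); T.site_sig.push_back(wp(r,1)); T.site_r0.push_back(wp(r,2));
  }
  IntegerVector pi = tl["posres_i"]; NumericMatrix pp = tl["posres_par"];
  for (int r = 0; r < pi.size(); ++r) {
    T.pr_i.push_back(pi[r]);
    T.pr_x.push_back(pp(r,0)); T.pr_y.push_back(pp(r,1));
    T.pr_z.push_back(pp(r,2)); T.pr_k.push_back(pp(r,3));
  }
}

Topology build_topology(const List& topo, const List& state_terms) {
  Topology T;
  NumericVector radius = topo["radius"], mass_v = topo["mass"],
                ev_v = topo["ev_eps"],
                qd = topo["charge_dna"], qp = topo["charge_pro"];
  IntegerVector is_dna = topo["is_dna"], mobile = topo["mobile"];
  T.n = radius.size();
  T.radius.assign(radius.begin(), radius.end());
  T.mass.assign(mass_v.begin(), mass_v.end());
  T.ev_eps.assign(ev_v.begin(), ev_v.end());
  T.qd.assign(qd.begin(), qd.end());
  T.qp.assign(qp.begin(), qp.end());
  T.is_dna.assign(is_dna.begin(), is_dna.end());
  T.mobile.assign(mobile.begin(), mobile.end());
  read_term_matrices(topo, T);
  T.eps_ev  = as<double>(topo["eps_ev"]);
  T.lB      = as<double>(topo["lB"]);
  T.kappa   = as<double>(topo["kappa"]);
  T.r_cut_dh = as<double>(topo["r_cut_dh"]);
  IntegerMatrix ex = topo["excl_ij"];
  T.excl_adj.assign(T.n, std::vector<int>());
  for (int r = 0; r < ex.nrow(); ++r) {
    int i = ex(r,0), j = ex(r,1);
    T.excl_adj[i].push_back(j);
    T.excl_adj[j].push_back(i);
  }
  // state-dependent
  IntegerVector wl = state_terms["well_loop"];
  IntegerVector wm = state_terms["well_mate"];
  NumericMatrix wpar = state_terms["well_par"];
  for (int r = 0; r < wl.size(); ++r) {
    T.well_loop.push_back(wl[r]);
    T.well_mate.push_back(r < wm.size() ? wm[r] : -1);
    T.well_eps.push_back(wpar(r,0)); T.well_sig.push_back(wpar(r,1));
    T.well_r0.push_back(wpar(r,2)); T.well_brk.push_back(wpar(r,3));
  }
  IntegerVector el = state_terms["eligible"];
  T.eligible.assign(el.begin(), el.end());
  IntegerMatrix nm = state_terms["native_ij"]; NumericMatrix np = state_terms["native_par"];
  for (int r = 0; r < nm.nrow(); ++r) {
    T.nat_i.push_back(nm(r,0)); T.nat_j.push_back(nm(r,1));
    T.nat_r0.push_back(np(r,0)); T.nat_k.push_back(np(r,1));
  }
  T.nat_dcap = as<double>(state_terms["native_dcap"]);
  T.well_ramp = as<double>(state_terms["well_ramp"]);
  T.well_delay = as<double>(state_terms["well_delay"]);
  T.well_refract_steps = as<double>(state_terms["well_refract"]);
  IntegerVector li = state_terms["loop_pr_i"];
  NumericMatrix lp = state_terms["loop_pr_par"];
  for (int r = 0; r < li.size(); ++r) {
    T.lpr_i.push_back(li[r]);
    T.lpr_x.push_back(lp(r,0)); T.lpr_y.push_back(lp(r,1));
    T.lpr_z.push_back(lp(r,2)); T.lpr_k.push_back(lp(r,3));
  }
  return T;
}

// ---------------------------------------------------------------- RNG
// xoshiro-free: explicit 64-bit SplitMix + polar Gaussian with cached value,
// so the stream is fully determined by the seed and the draw count.
struct Rng {
  uint64_t s;
  bool have_cached = false;
  double cached = 0.0;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next_u64() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    cached = r * std::sin(a); have_cached = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------- neighbor lists
struct NeighborLists {
  std::vector<int> ev_i, ev_j;
  std::vector<int> dh_i, dh_j;
  std::vector<double> dh_qq;
  // persistent buffers (no per-rebuild allocation)
  std::vector<int> head, nxt, charged;
};

void build_lists(const Topology& T, const std::vector<double>& x,
                 double skin, NeighborLists& nl) {
  nl.ev_i.clear(); nl.ev_j.clear();
  nl.dh_i.clear(); nl.dh_j.clear(); nl.dh_qq.clear();
  const int n = T.n;
  // cell list for excluded volume
  double rc_ev_max = 0.0;
  for (int i = 0; i < n; ++i) rc_ev_max = std::max(rc_ev_max, T.radius[i]);
  rc_ev_max = 2.0 * rc_ev_max * 1.5 + skin;
  double xmin[3] = {1e30,1e30,1e30}, xmax[3] = {-1e30,-1e30,-1e30};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xmin[d] = std::min(xmin[d], x[3*i+d]);
      xmax[d] = std::max(xmax[d], x[3*i+d]);
    }
  double cell = std::max(rc_ev_max, 1e-6);
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((xmax[d] - xmin[d]) / cell) + 1);
  size_t ncell = (size_t)nc[0]*nc[1]*nc[2];
  nl.head.assign(ncell, -1);
  nl.nxt.resize(n);
  auto cidx = [&](int i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)std::floor((x[3*i+d] - xmin[d]) / cell);
      c[d] = std::min(std::max(c[d], 0), nc[d]-1);
    }
    return (size_t)(c[0] + nc[0]*(c[1] + nc[1]*c[2]));
  };
  for (int i = 0; i < n; ++i) {
    size_t c = cidx(i);
    nl.nxt[i] = nl.head[c];
    nl.head[c] = i;
  }
  const double* RAD = T.radius.data();
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int me0 = nl.head[cx + nc[0]*(cy + nc[1]*cz)];
        if (me0 < 0) continue;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = (dz==0 ? 0 : -1); dy <= 1; ++dy)
            for (int dx = ((dz==0 && dy==0) ? 0 : -1); dx <= 1; ++dx) {
              int ox = cx+dx, oy = cy+dy, oz = cz+dz;
              if (ox < 0 || oy < 0 || oz < 0 || ox >= nc[0] || oy >= nc[1] || oz >= nc[2]) continue;
              int other0 = nl.head[ox + nc[0]*(oy + nc[1]*oz)];
              bool same = (dx==0 && dy==0 && dz==0);
              for (int i = me0; i >= 0; i = nl.nxt[i]) {
                double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
                double ri = RAD[i];
                bool mi = T.mobile[i];
                for (int j = same ? nl.nxt[i] : other0; j >= 0; j = nl.nxt[j]) {
                  if (!mi && !T.mobile[j]) continue;
                  double ddx = xi-x[3*j], ddy = yi-x[3*j+1], ddz = zi-x[3*j+2];
                  double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
                  double rl = 1.5 * (ri + RAD[j]) + skin;
                  if (r2 > rl * rl) continue;
                  if (excluded(T, i, j)) continue;
                  nl.ev_i.push_back(i); nl.ev_j.push_back(j);
                }
              }
            }
      }
  // Debye-Hueckel list over charged beads only (brute force; few of them)
  if (nl.charged.empty())
    for (int i = 0; i < n; ++i)
      if (T.qd[i] != 0.0 || T.qp[i] != 0.0) nl.charged.push_back(i);
  std::vector<int>& ch = nl.charged;
  // z-sorted sweep: the assemblies are elongated along the channel axis,
  // so pruning on the axial separation removes most candidate pairs
  std::sort(ch.begin(), ch.end(),
            [&](int a, int b) { return x[3*a+2] < x[3*b+2]; });
  double rdh = T.r_cut_dh + skin, rdh2 = rdh * rdh;
  for (size_t a = 0; a < ch.size(); ++a) {
    int i = ch[a];
    double zi = x[3*i+2];
    for (size_t b = a+1; b < ch.size(); ++b) {
      int j = ch[b];
      if (x[3*j+2] - zi > rdh) break;
      if (!T.mobile[i] && !T.mobile[j]) continue;
      double ddx = x[3*i]-x[3*j], ddy = x[3*i+1]-x[3*j+1], ddz = x[3*i+2]-x[3*j+2];
      double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
      if (r2 > rdh2) continue;
      if (excluded(T, i, j)) continue;
      double qq = (T.is_dna[i] && T.is_dna[j]) ? T.qd[i]*T.qd[j] : T.qp[i]*T.qp[j];
      if (qq == 0.0) continue;
      nl.dh_i.push_back(i); nl.dh_j.push_back(j); nl.dh_qq.push_back(qq * T.lB);
    }
  }
}

// ---------------------------------------------------------------- forces
struct EnergyParts {
  double bond = 0, angle = 0, morse = 0, stack = 0, site = 0, posres = 0,
         ev = 0, dh = 0, well = 0, native = 0;
  double total() const {
    return bond + angle + morse + stack + site + posres + ev + dh + well + native;
  }
};

// accumulate forces (gradient of total energy, negated) into f
EnergyParts compute_forces(const Topology& T, const std::vector<double>& x,
                           const NeighborLists& nl, std::vector<double>& f,
                           std::vector<int>* well_partner = nullptr,
                           std::vector<double>* well_age = nullptr,
                           std::vector<double>* well_refract = nullptr) {
  EnergyParts E;
  std::fill(f.begin(), f.end(), 0.0);
  const double* X = x.data();
  auto addpair = [&](int i, int j, double fr_over_r,
                     double dx, double dy, double dz) {
    // fr_over_r = -(dU/dr)/r ; force on i along +d (d = xi - xj)
    f[3*i]   += fr_over_r * dx; f[3*i+1] += fr_over_r * dy; f[3*i+2] += fr_over_r * dz;
    f[3*j]   -= fr_over_r * dx; f[3*j+1] -= fr_over_r * dy; f[3*j+2] -= fr_over_r * dz;
  };
  // bonds
  for (size_t t = 0; t < T.bond_i.size(); ++t) {
    int i = T.bond_i[t], j = T.bond_j[t];
    double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double d = r - T.bond_r0[t];
    E.bond += 0.5 * T.bond_k[t] * d * d;
    if (r > 1e-12) addpair(i, j, -T.bond_k[t]*d/r, dx, dy, dz);
  }
  // angles: cosine form U = k (1 + cos theta), the harmonic-equivalent
  // bending term for straight (theta0 = pi) chains without trigonometric
  // singularities
  for (size_t t = 0; t < T.ang_i.size(); ++t) {
    int i = T.ang_i[t], j = T.ang_j[t], k = T.ang_k[t];
    double rij[3] = {X[3*i]-X[3*j], X[3*i+1]-X[3*j+1], X[3*i+2]-X[3*j+2]};
    double rkj[3] = {X[3*k]-X[3*j], X[3*k+1]-X[3*j+1], X[3*k+2]-X[3*j+2]};
    double n2ij = rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2];
    double n2kj = rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2];
    if (n2ij < 1e-18 || n2kj < 1e-18) continue;
    double nij = std::sqrt(n2ij), nkj = std::sqrt(n2kj);
    double cs = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij*nkj);
    E.angle += T.ang_kk[t] * (1.0 + cs);
    // force_i = -k * d(cos theta)/dr_i
    double coef = -T.ang_kk[t];
    for (int dd = 0; dd < 3; ++dd) {
      double gi = coef * (rkj[dd]/(nij*nkj) - cs*rij[dd]/n2ij);
      double gk = coef * (rij[dd]/(nij*nkj) - cs*rkj[dd]/n2kj);
      f[3*i+dd] += gi;
      f[3*k+dd] += gk;
      f[3*j+dd] -= (gi + gk);
    }
  }
  // Morse pairs + stacking
  auto morse_term = [&](int i, int j, double eps, double alpha, double r0, double& acc) {
    double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double e = fexp(-alpha*(r - r0));
    double om = 1.0 - e;
    acc += eps * (om*om - 1.0);
    double dUdr = 2.0 * eps * alpha * e * om;
    if (r > 1e-12) addpair(i, j, -dUdr/r, dx, dy, dz);
  };
  for (size_t t = 0; t < T.mor_i.size(); ++t)
    morse_term(T.mor_i[t], T.mor_j[t], T.mor_eps[t], T.mor_alpha[t], T.mor_r0[t], E.morse);
  for (size_t t = 0; t < T.stk_i.size(); ++t)
    morse_term(T.stk_i[t], T.stk_j[t], T.stk_eps[t], T.stk_alpha[t], T.stk_r0[t], E.stack);
  // Gaussian site wells
  auto gauss_term = [&](int i, int j, double eps, double sig, double r0, double& acc) {
    double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double d = r - r0;
    double ex = fexp(-d*d/(2.0*sig*sig));
    acc += -eps * ex;
    double dUdr = eps * d / (sig*sig) * ex;
    if (r > 1e-12) addpair(i, j, -dUdr/r, dx, dy, dz);
  };
  for (size_t t = 0; t < T.site_i.size(); ++t)
    gauss_term(T.site_i[t], T.site_j[t], T.site_eps[t], T.site_sig[t], T.site_r0[t], E.site);
  // position restraints
  for (size_t t = 0; t < T.pr_i.size(); ++t) {
    int i = T.pr_i[t];
    double dx = X[3*i]-T.pr_x[t], dy = X[3*i+1]-T.pr_y[t], dz = X[3*i+2]-T.pr_z[t];
    E.posres += 0.5 * T.pr_k[t] * (dx*dx+dy*dy+dz*dz);
    f[3*i]   -= T.pr_k[t]*dx; f[3*i+1] -= T.pr_k[t]*dy; f[3*i+2] -= T.pr_k[t]*dz;
  }
  // excluded volume: truncated-shifted r^-12 with a linearised core below
  // 0.85 sigma (bounded forces keep deep thermal overlaps integrable)
  for (size_t t = 0; t < nl.ev_i.size(); ++t) {
    int i = nl.ev_i[t], j = nl.ev_j[t];
    double sig = T.radius[i] + T.radius[j];
    double eps_ij = std::sqrt(T.ev_eps[i] * T.ev_eps[j]);
    double rc = 1.5 * sig;
    double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
    double r2 = dx*dx+dy*dy+dz*dz;
    if (r2 > rc*rc || r2 < 1e-12) continue;
    const double shift = 1.0 / 129.746337890625; // (1/1.5)^12
    double rmin = 0.85 * sig;
    double r = std::sqrt(r2);
    if (r >= rmin) {
      double s2 = sig*sig / r2;
      double s6 = s2*s2*s2, s12 = s6*s6;
      E.ev += eps_ij * (s12 - shift);
      addpair(i, j, 12.0 * eps_ij * s12 / r2, dx, dy, dz);
    } else {
      // U(r) = U(rmin) + F0 (rmin - r), continuous in U and F
      double s12m = std::pow(1.0/0.85, 12.0);
      double F0 = 12.0 * eps_ij * s12m / rmin;
      E.ev += eps_ij * (s12m - shift) + F0 * (rmin - r);
      addpair(i, j, F0 / r, dx, dy, dz);
    }
  }
  // Debye-Hueckel, energy-shifted at r_cut
  {
    double rc = T.r_cut_dh;
    double shift_fac = std::exp(-T.kappa*rc) / rc;
    for (size_t t = 0; t < nl.dh_i.size(); ++t) {
      int i = nl.dh_i[t], j = nl.dh_j[t];
      double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
      double r2 = dx*dx+dy*dy+dz*dz;
      if (r2 > rc*rc || r2 < 1e-12) continue;
      double r = std::sqrt(r2);
      double pre = nl.dh_qq[t];
      double er = fexp(-T.kappa*r);
      E.dh += pre * (er/r - shift_fac);
      double dUdr = -pre * er * (T.kappa*r + 1.0) / r2;
      addpair(i, j, -dUdr/r, dx, dy, dz);
    }
  }
  // switchable hydrogen-bond wells: dynamic bonds to eligible phosphates.
  // A well binds the nearest eligible phosphate and holds that partner
  // until strained beyond r0 + 3 sigma, then rebinds to the current
  // nearest; a stateless evaluation (well_partner all -1) binds nearest.
  for (size_t w = 0; w < T.well_loop.size(); ++w) {
    int i = T.well_loop[w];
    int cur = well_partner ? (*well_partner)[w] : -1;
    if (well_refract && (*well_refract)[w] > 0.0) {
      if (well_partner) (*well_partner)[w] = -1;
      continue;                      // released: no grip during refractory
    }
    double brk = T.well_r0[w] + T.well_brk[w] * T.well_sig[w];
    if (cur >= 0) {
      double dx = X[3*i]-X[3*cur], dy = X[3*i+1]-X[3*cur+1], dz = X[3*i+2]-X[3*cur+2];
      if (dx*dx+dy*dy+dz*dz > brk*brk) {
        cur = -1;
        if (well_refract) (*well_refract)[w] = T.well_refract_steps;
      }
    }
    if (cur < 0) {
      // phosphates are exclusive: no two wells may share a partner
      double bd2 = 1e30;
      for (size_t e = 0; e < T.eligible.size(); ++e) {
        int j = T.eligible[e];
        bool taken = false;
        if (well_partner)
          for (size_t v = 0; v < well_partner->size(); ++v)
            if (v != w && (*well_partner)[v] == j) { taken = true; break; }
        if (taken) continue;
        double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
        double d2 = dx*dx+dy*dy+dz*dz;
        if (d2 < bd2) { bd2 = d2; cur = j; }
      }
    }
    if (well_partner) (*well_partner)[w] = cur;
    if (cur >= 0) {
      double eps = T.well_eps[w];
      if (well_age) {
        double m = ((*well_age)[w] - T.well_delay) / T.well_ramp;
        if (m < 1.0) eps *= std::max(0.0, m);
        if (eps == 0.0) { continue; }
      }
      gauss_term(i, cur, eps, T.well_sig[w], T.well_r0[w], E.well);
    }
  }
  // state-dependent native restraints: harmonic near the rest length,
  // linear beyond nat_dcap so the pull on a far-from-target loop is a
  // bounded force (the loop escorts the gripped DNA instead of snapping)
  for (size_t t = 0; t < T.nat_i.size(); ++t) {
    int i = T.nat_i[t], j = T.nat_j[t];
    double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double d = r - T.nat_r0[t];
    double k = T.nat_k[t], dc = T.nat_dcap;
    double ad = std::fabs(d);
    double fr; // -dU/dr
    if (ad <= dc) {
      E.native += 0.5 * k * d * d;
      fr = -k * d;
    } else {
      E.native += k * dc * (ad - 0.5 * dc);
      fr = -k * dc * (d > 0 ? 1.0 : -1.0);
    }
    if (r > 1e-12) addpair(i, j, fr/r, dx, dy, dz);
  }
  // capped loop position restraints (the conformational targets)
  for (size_t t = 0; t < T.lpr_i.size(); ++t) {
    int i = T.lpr_i[t];
    double dx = X[3*i]-T.lpr_x[t], dy = X[3*i+1]-T.lpr_y[t], dz = X[3*i+2]-T.lpr_z[t];
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double k = T.lpr_k[t], dc = T.nat_dcap;
    if (r <= dc) {
      E.native += 0.5 * k * r * r;
      f[3*i]   -= k*dx; f[3*i+1] -= k*dy; f[3*i+2] -= k*dz;
    } else {
      E.native += k * dc * (r - 0.5 * dc);
      double fr = k * dc / r;
      f[3*i]   -= fr*dx; f[3*i+1] -= fr*dy; f[3*i+2] -= fr*dz;
    }
  }
  // frozen beads feel no net force
  for (int i = 0; i < T.n; ++i)
    if (!T.mobile[i]) { f[3*i] = f[3*i+1] = f[3*i+2] = 0.0; }
  return E;
}

} // namespace

// [[Rcpp::export(name = ".cg_energy_cpp")]]
List cg_energy_cpp(NumericMatrix coords, List topo, List state_terms) {
  Topology T = build_topology(topo, state_terms);
  std::vector<double> x(3*T.n), f(3*T.n);
  for (int i = 0; i < T.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i,d);
  NeighborLists nl;
  build_lists(T, x, 0.0, nl);
  std::vector<int> wp(T.well_loop.size(), -1);
  EnergyParts E = compute_forces(T, x, nl, f, &wp);
  NumericMatrix fm(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int d = 0; d < 3; ++d) fm(i,d) = f[3*i+d];
  return List::create(
    _["total"] = E.total(),
    _["bond"] = E.bond, _["angle"] = E.angle, _["morse"] = E.morse,
    _["stack"] = E.stack, _["site"] = E.site, _["posres"] = E.posres,
    _["ev"] = E.ev, _["dh"] = E.dh, _["well"] = E.well, _["native"] = E.native,
    _["forces"] = fm,
    _["well_partner"] = IntegerVector(wp.begin(), wp.end()));
}

// [[Rcpp::export(name = ".cg_minimize_cpp")]]
List cg_minimize_cpp(NumericMatrix coords, List topo, List state_terms,
                     int max_iter, double step0, double tol) {
  Topology T = build_topology(topo, state_terms);
  std::vector<double> x(3*T.n), f(3*T.n);
  for (int i = 0; i < T.n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = coords(i,d);
  NeighborLists nl;
  double step = step0;
  build_lists(T, x, 0.5, nl);
  EnergyParts E = compute_forces(T, x, nl, f);
  double e_prev = E.total();
  int it = 0;
  for (; it < max_iter; ++it) {
    double fmax = 0.0;
    for (int i = 0; i < T.n; ++i)
      if (T.mobile[i])
        for (int d = 0; d < 3; ++d) fmax = std::max(fmax, std::fabs(f[3*i+d]));
    if (fmax < tol) break;
    // steepest descent with displacement cap
    std::vector<double> xt(x);
    double cap = 0.1;
    double scale = std::min(step, cap / fmax);
    for (int i = 0; i < T.n; ++i)
      if (T.mobile[i])
        for (int d = 0; d < 3; ++d) xt[3*i+d] += scale * f[3*i+d];
    build_lists(T, xt, 0.5, nl);
    std::vector<double> ft(3*T.n);
    EnergyParts Et = compute_forces(T, xt, nl, ft);
    if (Et.total() <= e_prev) {
      x.swap(xt); f.swap(ft); e_prev = Et.total();
      step = std::min(step * 1.2, 1.0);
    } else {
      step *= 0.5;
      if (step < 1e-8) break;
      build_lists(T, x, 0.5, nl);
      compute_forces(T, x, nl, f);
    }
  }
  NumericMatrix cm(T.n, 3);
  for (int i = 0; i < T.n; ++i)
    for (int d = 0; d < 3; ++d) cm(i,d) = x[3*i+d];
  return List::create(_["coords"] = cm, _["energy"] = e_prev, _["iterations"] = it);
}

// [[Rcpp::export(name = ".cg_run_segment_cpp")]]
List cg_run_segment_cpp(NumericMatrix coords, NumericMatrix vels,
                        List topo, List state_terms, List opts) {
  Topology T = build_topology(topo, state_terms);
  const int n = T.n;
  const int n_steps   = as<int>(opts["n_steps"]);
  double dt           = as<double>(opts["dt"]);
  const double gamma  = as<double>(opts["gamma"]);
  const double temp   = as<double>(opts["temperature"]);
  const int sub       = std::max(1, as<int>(opts["subsample_every"]));
  const uint64_t seed = (uint64_t)as<double>(opts["seed"]);
  const int rebuild   = std::max(1, as<int>(opts["nlist_every"]));
  const double skin   = as<double>(opts["nlist_skin"]);
  const double fmax_allowed = as<double>(opts["force_overflow"]);

  std::vector<double> x(3*n), v(3*n), f(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { x[3*i+d] = coords(i,d); v[3*i+d] = vels(i,d); }

  Rng rng(seed * 0x9E3779B97f4A7C15ULL + 1ULL);
  NeighborLists nl;
  build_lists(T, x, skin, nl);
  IntegerVector wp0 = opts["well_partner"];
  std::vector<int> wp(wp0.begin(), wp0.end());
  if ((int)wp.size() != (int)T.well_loop.size())
    wp.assign(T.well_loop.size(), -1);
  NumericVector wa0 = opts["well_age"];
  std::vector<double> wa(wa0.begin(), wa0.end());
  if ((int)wa.size() != (int)T.well_loop.size())
    wa.assign(T.well_loop.size(), 1e12);
  NumericVector wr0 = opts["well_refract"];
  std::vector<double> wr(wr0.begin(), wr0.end());
  if ((int)wr.size() != (int)T.well_loop.size())
    wr.assign(T.well_loop.size(), 0.0);
  EnergyParts E = compute_forces(T, x, nl, f, &wp, &wa, &wr);

  int n_frames = n_steps / sub;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  IntegerVector frame_step(n_frames);
  NumericVector frame_energy(n_frames);
  IntegerMatrix frame_partner((int)T.well_loop.size(), n_frames);
  int fi = 0, dt_reductions = 0;

  double c1 = std::exp(-gamma * dt);
  std::vector<double> c2(n), inv_m(n);
  for (int i = 0; i < n; ++i) {
    inv_m[i] = 1.0 / T.mass[i];
    c2[i] = std::sqrt((1.0 - c1*c1) * temp * inv_m[i]);
  }
  const double half = 0.5;

  for (int s = 1; s <= n_steps; ++s) {
    // BAOAB
    for (int i = 0; i < n; ++i) if (T.mobile[i])
      for (int d = 0; d < 3; ++d) {
        v[3*i+d] += half * dt * f[3*i+d] * inv_m[i];
        x[3*i+d] += half * dt * v[3*i+d];
      }
    for (int i = 0; i < n; ++i) if (T.mobile[i])
      for (int d = 0; d < 3; ++d)
        v[3*i+d] = c1 * v[3*i+d] + c2[i] * rng.gauss();
    for (int i = 0; i < n; ++i) if (T.mobile[i])
      for (int d = 0; d < 3; ++d)
        x[3*i+d] += half * dt * v[3*i+d];
    if (s % rebuild == 0) build_lists(T, x, skin, nl);
    for (size_t w = 0; w < wa.size(); ++w) {
      wa[w] += 1.0;
      if (wr[w] > 0.0) wr[w] -= 1.0;
    }
    E = compute_forces(T, x, nl, f, &wp, &wa, &wr);
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) if (T.mobile[i])
      for (int d = 0; d < 3; ++d) fmax = std::max(fmax, std::fabs(f[3*i+d]));
    if (!std::isfinite(fmax)) {
      int bad = -1;
      for (int i = 0; i < n && bad < 0; ++i)
        for (int d = 0; d < 3; ++d)
          if (!std::isfinite(f[3*i+d])) { bad = i; break; }
      stop("non-finite force on bead %d at step %d", bad + 1, s);
    }
    if (fmax * dt > fmax_allowed) {
      // halve dt for stability; logged via counter
      dt *= 0.5; ++dt_reductions;
      c1 = std::exp(-gamma * dt);
      for (int i = 0; i < n; ++i)
        c2[i] = std::sqrt((1.0 - c1*c1) * temp * inv_m[i]);
    }
    for (int i = 0; i < n; ++i) if (T.mobile[i])
      for (int d = 0; d < 3; ++d)
        v[3*i+d] += half * dt * f[3*i+d] * inv_m[i];
    if (s % sub == 0 && fi < n_frames) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)fi * n * 3 + (R_xlen_t)i * 3 + d] = x[3*i+d];
      frame_step[fi] = s;
      frame_energy[fi] = E.total();
      for (size_t w = 0; w < wp.size(); ++w) frame_partner(w, fi) = wp[w];
      ++fi;
    }
  }
  NumericMatrix cm(n, 3), vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) { cm(i,d) = x[3*i+d]; vm(i,d) = v[3*i+d]; }
  frames.attr("dim") = IntegerVector::create(3, n, n_frames);
  return List::create(
    _["coords"] = cm, _["vels"] = vm,
    _["frames"] = frames, _["frame_step"] = frame_step,
    _["frame_energy"] = frame_energy,
    _["dt_final"] = dt, _["dt_reductions"] = dt_reductions,
    _["well_partner"] = IntegerVector(wp.begin(), wp.end()),
    _["frame_partner"] = frame_partner,
    _["well_age"] = NumericVector(wa.begin(), wa.end()),
    _["well_refract"] = NumericVector(wr.begin(), wr.end()),
    _["energy_final"] = E.total());
}

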