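// Coarse-grained bead-spring Langevin dynamics for a single polyampholyte
// chain with unscreened Coulomb interactions (open boundaries, direct
// O(N^2) pair sum). Reduced units: monomer size a = 1, k_B T = 1, e = 1.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Deterministic Gaussian stream: mt19937_64 (bit-exact per the C++
// standard) + hand-rolled Box-Muller, so trajectories are reproducible
// for a given seed independent of library implementation details.
struct GaussRNG {
  std::mt19937_64 eng;
  double spare;
  bool has_spare;
  explicit GaussRNG(uint64_t seed) : eng(seed), spare(0.0), has_spare(false) {}
  double unif() {  // in (0, 1]
    return ((eng() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

struct FF {
  int bond_type;        // 0 harmonic, 1 FENE
  double bond_k, bond_r0;   // harmonic: U = k/2 (r - r0)^2
  double fene_R0;           // FENE: U = -k R0^2/2 ln(1 - (r/R0)^2)
  double lj_eps, lj_cut;    // LJ (sigma = 1), energy-shifted at cutoff
  bool lj_on;
  double u;                 // Bjerrum length
};

static FF make_ff(List ff_list) {
  FF ff;
  ff.bond_type = as<int>(ff_list["bond_type"]);
  ff.bond_k = as<double>(ff_list["bond_k"]);
  ff.bond_r0 = as<double>(ff_list["bond_r0"]);
  ff.fene_R0 = as<double>(ff_list["fene_R0"]);
  ff.lj_eps = as<double>(ff_list["lj_eps"]);
  ff.lj_cut = as<double>(ff_list["lj_cut"]);
  ff.lj_on = as<bool>(ff_list["lj_on"]);
  ff.u = as<double>(ff_list["u"]);
  return ff;
}

// Accumulate forces (length-3n array, layout x0..xn-1,y0..,z0..) and
// energy components. Returns false on a singular/broken configuration.
static bool eval_ff(const double* x, int n, const int* q,
                    const std::vector<int>& charged, const FF& ff,
                    double* f, double& e_bond, double& e_pair,
                    double& e_coul, bool strict) {
  e_bond = e_pair = e_coul = 0.0;
  std::fill(f, f + 3 * n, 0.0);
  const double* X = x;
  const double* Y = x + n;
  const double* Z = x + 2 * n;
  double* FX = f;
  double* FY = f + n;
  double* FZ = f + 2 * n;
  const double rc2 = ff.lj_cut * ff.lj_cut;
  double sr6c = 1.0 / (rc2 * rc2 * rc2);
  const double eshift = 4.0 * ff.lj_eps * (sr6c * sr6c - sr6c);
  // bonds
  for (int i = 0; i < n - 1; ++i) {
    double dx = X[i + 1] - X[i], dy = Y[i + 1] - Y[i], dz = Z[i + 1] - Z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double fr;  // dU/dr
    if (ff.bond_type == 1) {
      double s = r2 / (ff.fene_R0 * ff.fene_R0);
      if (s >= 1.0) return false;
      e_bond += -0.5 * ff.bond_k * ff.fene_R0 * ff.fene_R0 * std::log(1.0 - s);
      fr = ff.bond_k * r / (1.0 - s);
    } else {
      double d = r - ff.bond_r0;
      e_bond += 0.5 * ff.bond_k * d * d;
      fr = ff.bond_k * d;
    }
    if (r > 1e-12) {
      double c = fr / r;
      FX[i] += c * dx; FX[i + 1] -= c * dx;
      FY[i] += c * dy; FY[i + 1] -= c * dy;
      FZ[i] += c * dz; FZ[i + 1] -= c * dz;
    }
  }
  // excluded volume: LJ within cutoff over all pairs
  if (ff.lj_on) {
    for (int i = 0; i < n - 1; ++i) {
      const double xi = X[i], yi = Y[i], zi = Z[i];
      double fxi = 0.0, fyi = 0.0, fzi = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double dx = X[j] - xi, dy = Y[j] - yi, dz = Z[j] - zi;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) {
          double inv2 = 1.0 / r2;
          double sr6 = inv2 * inv2 * inv2;
          e_pair += 4.0 * ff.lj_eps * (sr6 * sr6 - sr6) - eshift;
          double g = -24.0 * ff.lj_eps * (2.0 * sr6 * sr6 - sr6) * inv2;
          fxi += g * dx; FX[j] -= g * dx;
          fyi += g * dy; FY[j] -= g * dy;
          fzi += g * dz; FZ[j] -= g * dz;
        }
      }
      FX[i] += fxi; FY[i] += fyi; FZ[i] += fzi;
    }
  }
  // Coulomb over charged pairs only, no cutoff
  const int nc = static_cast<int>(charged.size());
  for (int a = 0; a < nc - 1; ++a) {
    const int i = charged[a];
    const double xi = X[i], yi = Y[i], zi = Z[i];
    const double qi = ff.u * q[i];
    double fxi = 0.0, fyi = 0.0, fzi = 0.0;
    for (int b = a + 1; b < nc; ++b) {
      const int j = charged[b];
      double dx = X[j] - xi, dy = Y[j] - yi, dz = Z[j] - zi;
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r < 1e-6) {
        if (strict) return false;
        r = 1e-6; r2 = 1e-12;
      }
      double qq = qi * q[j];
      e_coul += qq / r;
      double g = -qq / (r2 * r);
      fxi += g * dx; FX[j] -= g * dx;
      fyi += g * dy; FY[j] -= g * dy;
      fzi += g * dz; FZ[j] -= g * dz;
    }
    FX[i] += fxi; FY[i] += fyi; FZ[i] += fzi;
  }
  return true;
}

static std::vector<int> charged_indices(const IntegerVector& q) {
  std::vector<int> idx;
  for (int i = 0; i < q.size(); ++i)
    if (q[i] != 0) idx.push_back(i);
  return idx;
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix coords, IntegerVector charges, List ff_list) {
  FF ff = make_ff(ff_list);
  const int n = coords.nrow();
  NumericMatrix force(n, 3);
  std::vector<int> charged = charged_indices(charges);
  double eb, ep, ec;
  bool ok = eval_ff(REAL(coords), n, INTEGER(charges), charged, ff,
                    REAL(force), eb, ep, ec, true);
  if (!ok)
    stop("singular configuration: overlapping charged beads (r < 1e-6) or "
         "FENE bond beyond maximum extension");
  return List::create(_["bonded"] = eb, _["excluded_volume"] = ep,
                      _["coulomb"] = ec, _["total"] = eb + ep + ec,
                      _["forces"] = force);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords0, IntegerVector charges,
                      List ff_list, double dt, int n_steps, double friction,
                      int seed, int save_every) {
  FF ff = make_ff(ff_list);
  const int n = coords0.nrow();
  const int n3 = 3 * n;
  NumericMatrix x = clone(coords0);
  std::vector<double> v(n3), f(n3);
  std::vector<int> charged = charged_indices(charges);
  const int* q = INTEGER(charges);
  double* xp = REAL(x);
  GaussRNG rng(static_cast<uint64_t>(seed));
  for (int i = 0; i < n3; ++i) v[i] = rng.gauss();  // kT = 1, m = 1

  double eb, ep, ec;
  if (!eval_ff(xp, n, q, charged, ff, f.data(), eb, ep, ec, false))
    stop("initial configuration violates the FENE extension limit");

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  const double hdt = 0.5 * dt;
  const int n_saved = n_steps / save_every;
  List frames(n_saved);
  NumericVector times(n_saved), e_bond(n_saved), e_pair(n_saved),
      e_coul(n_saved), e_kin(n_saved), rg(n_saved);
  int k = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB splitting
    for (int i = 0; i < n3; ++i) {
      v[i] += hdt * f[i];
      xp[i] += hdt * v[i];
    }
    for (int i = 0; i < n3; ++i) {
      v[i] = c1 * v[i] + c2 * rng.gauss();
      xp[i] += hdt * v[i];
    }
    if (!eval_ff(xp, n, q, charged, ff, f.data(), eb, ep, ec, false))
      stop("numerical instability at step %d (FENE bond broke): reduce the "
           "timestep (stability requires timestep <= 0.01 in reduced units)",
           step);
    for (int i = 0; i < n3; ++i) v[i] += hdt * f[i];

    if (step % save_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < n3; ++i) ke += 0.5 * v[i] * v[i];
      double cx = 0.0, cy = 0.0, cz = 0.0;
      for (int i = 0; i < n; ++i) {
        cx += xp[i]; cy += xp[i + n]; cz += xp[i + 2 * n];
      }
      cx /= n; cy /= n; cz /= n;
      double s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double dx = xp[i] - cx, dy = xp[i + n] - cy, dz = xp[i + 2 * n] - cz;
        s2 += dx * dx + dy * dy + dz * dz;
      }
      if (!std::isfinite(eb + ep + ec) || !std::isfinite(s2))
        stop("energy divergence at step %d: reduce the timestep "
             "(stability requires timestep <= 0.01 in reduced units)", step);
      frames[k] = clone(x);
      times[k] = step * dt;
      e_bond[k] = eb; e_pair[k] = ep; e_coul[k] = ec; e_kin[k] = ke;
      rg[k] = std::sqrt(s2 / n);
      ++k;
    }
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["e_bond"] = e_bond, _["e_pair"] = e_pair,
                      _["e_coul"] = e_coul, _["e_kin"] = e_kin,
                      _["rg"] = rg, _["final"] = x);
}
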