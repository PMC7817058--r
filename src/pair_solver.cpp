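#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Steady states of the two-drug mass-action system.
//
// At fixed growth rate lambda the unbound-ribosome pool is pinned by the
// first growth law (r_u = r_min + lambda/kappa_t).  Given the two
// intracellular drug concentrations, the three bound-ribosome pools
// (r_bA, r_bB, r_d) satisfy a linear system that solves in closed form
// with strictly positive denominators; the inner problem is therefore a
// 2-D root find in (a_A, a_B), handled by Newton with finite-difference
// Jacobian plus a bulletproof coordinate-bisection fallback (each drug
// balance is positive at a_i = 0 and negative for large a_i).  The
// ribosome balance residual
//    g(lambda) = r_u + r_bA + r_bB + r_d - r_tot(lambda)
// then defines the fixed points; the largest root of g on (0, lambda0] is
// the upper-branch (population-observable) steady state.  Roots are
// located by a downward scan with detection of near-fold dips, then
// bisection.

struct Pars {
  double pinA, poutA, konA, koffA, vA, kA;   // drug A transport/binding/CERG
  double pinB, poutB, konB, koffB, vB, kB;   // drug B
  double donA, donB, doffA, doffB;           // second-binding-step modifiers
  double kappa, rmin, rdr, lam0;             // growth laws (rdr = delta_r)
  double rtot_slope;                         // dr*(1/lam0 - 1/(kappa*dr))
  double rmax;
  double aexA, aexB;                         // external concentrations
};

struct State {
  double aA, aB, rbA, rbB, rd;
  bool ok;
};

static inline double rtot_of(const Pars& p, double lam) {
  return p.rmax - lam * p.rtot_slope;
}

// bound pools given the intracellular drug levels: exact linear solve
static inline void r_of_a(const Pars& p, double lam, double aA, double aB,
                          double* rbA, double* rbB, double* rd) {
  double free = lam / p.kappa;
  double DA = lam + p.koffA + p.donB * p.konB * aB;
  double DB = lam + p.koffB + p.donA * p.konA * aA;
  double dKA = p.doffA * p.koffA, dKB = p.doffB * p.koffB;
  double sA = p.konA * aA * free, sB = p.konB * aB * free;
  double cA = p.donA * p.konA * aA, cB = p.donB * p.konB * aB;
  double den = lam + dKA + dKB - cA * dKA / DB - cB * dKB / DA;
  double num = cA * sB / DB + cB * sA / DA;
  double rdv = num / den;
  *rd = rdv;
  *rbA = (sA + dKB * rdv) / DA;
  *rbB = (sB + dKA * rdv) / DB;
}

// intracellular drug balances with the bound pools eliminated exactly
static inline void drug_balance(const Pars& p, double lam, double aA,
                                double aB, double* H1, double* H2) {
  double free = lam / p.kappa, lamrel = lam / p.lam0;
  double rbA, rbB, rd;
  r_of_a(p, lam, aA, aB, &rbA, &rbB, &rd);
  double mmA = (p.vA > 0) ? p.vA * lamrel * aA / (aA + p.kA) : 0.0;
  double mmB = (p.vB > 0) ? p.vB * lamrel * aB / (aB + p.kB) : 0.0;
  *H1 = -(lam + p.poutA + p.konA * free) * aA + p.koffA * rbA +
        p.doffA * p.koffA * rd - p.donA * p.konA * aA * rbB +
        p.pinA * p.aexA - mmA;
  *H2 = -(lam + p.poutB + p.konB * free) * aB + p.koffB * rbB +
        p.doffB * p.koffB * rd - p.donB * p.konB * aB * rbA +
        p.pinB * p.aexB - mmB;
}

// bisection on one drug balance in its own concentration (other fixed);
// H_i is positive at a_i = 0 and eventually negative, so a bracket always
// exists
static double coord_solve(const Pars& p, double lam, bool drugA,
                          double other, double start) {
  double H1, H2;
  auto val = [&](double a) {
    if (drugA) drug_balance(p, lam, a, other, &H1, &H2);
    else drug_balance(p, lam, other, a, &H1, &H2);
    return drugA ? H1 : H2;
  };
  if (val(0.0) <= 0.0) return 0.0;
  double hi = (start > 0) ? 2.0 * start : 1.0;
  int k = 0;
  while (val(hi) > 0.0 && k++ < 200) hi *= 2.0;
  double lo = 0.0;
  for (int it = 0; it < 90; ++it) {
    double mid = 0.5 * (lo + hi);
    if (mid == lo || mid == hi) break;
    if (val(mid) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

static State inner_solve(const Pars& p, double lam, const State* warm) {
  double aA, aB;
  if (warm && warm->ok) {
    aA = warm->aA; aB = warm->aB;
  } else {
    aA = p.aexA * p.pinA / (p.poutA + lam);
    aB = p.aexB * p.pinB / (p.poutB + lam);
  }
  double H1, H2;
  drug_balance(p, lam, aA, aB, &H1, &H2);
  double scale = 1.0 + p.pinA * p.aexA + p.pinB * p.aexB;
  double tol = 1e-13 * scale;
  double fn = std::fabs(H1) + std::fabs(H2);

  for (int outer = 0; outer < 30 && fn > tol; ++outer) {
    // Newton phase (finite-difference 2x2 Jacobian, strict descent)
    for (int it = 0; it < 40 && fn > tol; ++it) {
      double hA = 1e-7 * (aA + 1e-3 * scale / (p.poutA + lam + 1));
      double hB = 1e-7 * (aB + 1e-3 * scale / (p.poutB + lam + 1));
      double f1a, f2a, f1b, f2b;
      drug_balance(p, lam, aA + hA, aB, &f1a, &f2a);
      drug_balance(p, lam, aA, aB + hB, &f1b, &f2b);
      double J11 = (f1a - H1) / hA, J21 = (f2a - H2) / hA;
      double J12 = (f1b - H1) / hB, J22 = (f2b - H2) / hB;
      double det = J11 * J22 - J12 * J21;
      if (det == 0.0 || !R_finite(det)) break;
      double dA = (-H1 * J22 + H2 * J12) / det;
      double dB = (-J11 * H2 + J21 * H1) / det;
      double step = 1.0;
      bool accepted = false;
      for (int ls = 0; ls < 30; ++ls) {
        double nA = aA + step * dA, nB = aB + step * dB;
        if (nA < 0) nA = 0;
        if (nB < 0) nB = 0;
        double g1, g2;
        drug_balance(p, lam, nA, nB, &g1, &g2);
        double gn = std::fabs(g1) + std::fabs(g2);
        if (gn < fn) {
          aA = nA; aB = nB; H1 = g1; H2 = g2; fn = gn;
          accepted = true;
          break;
        }
        step *= 0.5;
      }
      if (!accepted) break;
    }
    if (fn <= tol) break;
    // coordinate-bisection fallback: exact 1-D solves, globally stable
    for (int sweep = 0; sweep < 8; ++sweep) {
      aA = coord_solve(p, lam, true, aB, aA);
      aB = coord_solve(p, lam, false, aA, aB);
    }
    drug_balance(p, lam, aA, aB, &H1, &H2);
    fn = std::fabs(H1) + std::fabs(H2);
  }
  State s;
  s.aA = aA; s.aB = aB;
  r_of_a(p, lam, aA, aB, &s.rbA, &s.rbB, &s.rd);
  s.ok = true;
  return s;
}

static double gfun(const Pars& p, double lam, State* cache) {
  State s = inner_solve(p, lam, cache);
  if (cache) *cache = s;
  double ru = p.rmin + lam / p.kappa;
  return ru + s.rbA + s.rbB + s.rd - rtot_of(p, lam);
}

static double bisect(const Pars& p, double lo, double hi,
                     double glo, double ghi, State* cache) {
  // g(hi) > 0 > g(lo): root between; plain bisection to near machine eps
  (void)glo; (void)ghi;
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + hi);
    if (mid == lo || mid == hi) break;
    double gm = gfun(p, mid, cache);
    if (gm > 0) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

// refine a positive local minimum of g on [a, b] (a < b) by golden section;
// if the minimum dips below zero return the upper of the two new roots
static bool dip_root(const Pars& p, double a, double b, State* cache,
                     double* root) {
  const double gr = 0.61803398874989484820;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = gfun(p, x1, cache), f2 = gfun(p, x2, cache);
  for (int it = 0; it < 90; ++it) {
    if (f1 < 0) { *root = bisect(p, x1, b, f1, 1.0, cache); return true; }
    if (f2 < 0) { *root = bisect(p, x2, b, f2, 1.0, cache); return true; }
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = gfun(p, x1, cache);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = gfun(p, x2, cache);
    }
    if (b - a < 1e-14 * p.lam0) break;
  }
  return false;
}

// largest root of g(lambda) on (0, lambda0]; lam_warm (if > 0) is an upper
// branch value at a nearby, slightly lower, drug dose
static double largest_root(const Pars& p, double lam_warm, int nscan) {
  if (p.aexA <= 0 && p.aexB <= 0) return p.lam0;
  State cache; cache.ok = false;
  double h = p.lam0 / nscan;
  double lam_hi = p.lam0;
  if (lam_warm > 0 && lam_warm < p.lam0) {
    double cand = std::min(p.lam0, lam_warm + 5 * h);
    State tmp; tmp.ok = false;
    if (gfun(p, cand, &tmp) > 0) { lam_hi = cand; cache = tmp; }
  }
  double g_pp = NA_REAL, g_p = NA_REAL;
  double lam_pp = NA_REAL, lam_p = lam_hi;
  double g_hi = gfun(p, lam_hi, &cache);
  if (g_hi <= 0) {
    // warm start not above the root after all: restart from lambda0
    lam_p = p.lam0;
    g_hi = gfun(p, p.lam0, &cache);
    if (g_hi <= 0) return p.lam0;            // numerically drug-free
  }
  g_p = g_hi;
  double lam = lam_p - h;
  double lam_min = 1e-12 * p.lam0;
  bool geometric = false;
  while (lam > lam_min) {
    double g = gfun(p, lam, &cache);
    if (g <= 0) return bisect(p, lam, lam_p, g, g_p, &cache);
    if (R_finite(g_pp) && g_p < g_pp && g_p <= g) {
      // positive dip spanning [lam, lam_pp]: possible fold pair
      double root;
      if (dip_root(p, lam, lam_pp, &cache, &root)) return root;
    }
    g_pp = g_p; lam_pp = lam_p;
    g_p = g; lam_p = lam;
    if (!geometric && lam - h <= h) geometric = true;
    lam = geometric ? lam * 0.5 : lam - h;
  }
  return 0.0;                                // fully inhibited
}

static Pars build_pars(List parA, List parB, List deltas, List laws) {
  Pars p;
  p.pinA = parA["p_in"];  p.poutA = parA["p_out"];
  p.konA = parA["k_on"];  p.koffA = parA["k_off"];
  p.vA = parA["v_max_prime"]; p.kA = parA["k_rem"];
  p.pinB = parB["p_in"];  p.poutB = parB["p_out"];
  p.konB = parB["k_on"];  p.koffB = parB["k_off"];
  p.vB = parB["v_max_prime"]; p.kB = parB["k_rem"];
  p.donA = deltas["delta_on_A"];  p.donB = deltas["delta_on_B"];
  p.doffA = deltas["delta_off_A"]; p.doffB = deltas["delta_off_B"];
  p.kappa = laws["kappa_t"]; p.rmin = laws["r_min"];
  p.rdr = laws["delta_r"];   p.lam0 = laws["lambda0"];
  p.rmax = laws["r_max"];
  p.rtot_slope = p.rdr * (1.0 / p.lam0 - 1.0 / (p.kappa * p.rdr));
  p.aexA = p.aexB = 0.0;
  return p;
}

// [[Rcpp::export]]
List pair_point_cpp(double aexA, double aexB, List parA, List parB,
                    List deltas, List laws, double lam_warm = -1.0,
                    int nscan = 400) {
  Pars p = build_pars(parA, parB, deltas, laws);
  p.aexA = aexA; p.aexB = aexB;
  double lam = largest_root(p, lam_warm, nscan);
  State s; s.ok = false;
  double g = (lam > 0) ? gfun(p, lam, &s) : 0.0;
  if (lam <= 0) { s = inner_solve(p, 1e-12 * p.lam0, nullptr); }
  double ru = p.rmin + lam / p.kappa;
  return List::create(
    _["lambda"] = lam, _["y"] = lam / p.lam0,
    _["a_A"] = s.aA, _["a_B"] = s.aB,
    _["r_u"] = ru, _["r_b_A"] = s.rbA, _["r_b_B"] = s.rbB, _["r_d"] = s.rd,
    _["balance_residual"] = g);
}

// [[Rcpp::export]]
NumericMatrix pair_grid_cpp(NumericVector aexA_grid, NumericVector aexB_grid,
                            List parA, List parB, List deltas, List laws,
                            int nscan = 400) {
  Pars p = build_pars(parA, parB, deltas, laws);
  int nA = aexA_grid.size(), nB = aexB_grid.size();
  NumericMatrix y(nA, nB);
  double warm_col0 = -1.0;
  for (int i = 0; i < nA; ++i) {
    double warm = warm_col0;
    for (int j = 0; j < nB; ++j) {
      p.aexA = aexA_grid[i]; p.aexB = aexB_grid[j];
      double lam = largest_root(p, warm, nscan);
      y(i, j) = lam / p.lam0;
      warm = lam;
      if (j == 0) warm_col0 = lam;
    }
    Rcpp::checkUserInterrupt();
  }
  return y;
}
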