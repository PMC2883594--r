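// Core statistical-mechanics engine: partition sums over all non-overlapping
// binding configurations on a cis-regulatory region, per-site occupancies,
// and the 1-D output dynamics built on top of the promoter occupancy.
//
// Model representation (built in R by engine_model()):
//   L        region length (bp), 0-based left-anchored coordinates
//   fp_lo    RNAP footprint start (inclusive)
//   fp_hi    RNAP footprint end (exclusive); footprint = [fp_lo, fp_hi)
//   qR       basal RNAP statistical weight [RNAP]/Kd_promoter
//   wc, wa   cooperativity (TF-TF) and recruitment (TF-RNAP) factors
//   dc, da   max edge-to-edge gaps (bp) for cooperativity / recruitment
//   species  list of 3: starts (0-based), kd (nM), len (bp)
//
// Configuration weights follow the regulated-recruitment grand-canonical
// form: each bound TF contributes c/Kd, adjacent bound TFs with edge gap
// <= dc contribute a factor wc, RNAP contributes qR and a factor wa for
// every bound TF within gap <= da of its footprint. TFs whose site overlaps
// the footprint are mutually exclusive with RNAP.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int L, fp_lo, fp_hi, dc, da, nsp;
  double qR, wc, wa;
  // dense per-start arrays (length L; 0 where no site starts)
  std::vector<std::vector<double>> invkd;
  std::vector<std::vector<double>> onfac; // 0 = excluded with RNAP, else 1 or wa
  std::vector<int> len;
};

Model parse_model(const List& mod) {
  Model m;
  m.L = as<int>(mod["L"]);
  m.fp_lo = as<int>(mod["fp_lo"]);
  m.fp_hi = as<int>(mod["fp_hi"]);
  m.qR = as<double>(mod["qR"]);
  m.wc = as<double>(mod["wc"]);
  m.wa = as<double>(mod["wa"]);
  m.dc = as<int>(mod["dc"]);
  m.da = as<int>(mod["da"]);
  List species(mod["species"]);
  m.nsp = species.size();
  m.invkd.resize(m.nsp);
  m.onfac.resize(m.nsp);
  m.len.resize(m.nsp);
  for (int t = 0; t < m.nsp; ++t) {
    List sp(species[t]);
    IntegerVector starts = sp["starts"];
    NumericVector kd = sp["kd"];
    int lt = as<int>(sp["len"]);
    m.len[t] = lt;
    m.invkd[t].assign(m.L, 0.0);
    m.onfac[t].assign(m.L, 0.0);
    for (int i = 0; i < starts.size(); ++i) {
      int s = starts[i];
      if (s < 0 || s + lt > m.L) stop("site outside region");
      double k = kd[i];
      m.invkd[t][s] = R_finite(k) ? 1.0 / k : 0.0;
      int e = s + lt; // half-open end
      bool overlap = (s < m.fp_hi) && (e > m.fp_lo);
      if (overlap) {
        m.onfac[t][s] = 0.0;
      } else {
        int gap = (e <= m.fp_lo) ? (m.fp_lo - e) : (s - m.fp_hi);
        m.onfac[t][s] = (gap <= m.da) ? m.wa : 1.0;
      }
    }
  }
  return m;
}

// Partition sum of one branch. on = true restricts to RNAP-compatible
// configurations and applies recruitment factors (qR NOT included).
// If Efwd/Pfwd non-null they receive the forward DP arrays.
double branch_Z(const Model& m, const double* conc, bool on,
                std::vector<double>* Efwd = nullptr,
                std::vector<double>* Pfwd = nullptr) {
  std::vector<double> E(m.L + 1, 0.0), P(m.L + 1, 0.0);
  for (int e = 1; e <= m.L; ++e) {
    double acc = 0.0;
    for (int t = 0; t < m.nsp; ++t) {
      int s = e - m.len[t];
      if (s < 0) continue;
      double w = conc[t] * m.invkd[t][s];
      if (w <= 0.0) continue;
      if (on) {
        double f = m.onfac[t][s];
        if (f == 0.0) continue;
        w *= f;
      }
      int lo = s - m.dc - 1;
      double win = P[s] - (lo >= 0 ? P[lo] : 0.0);
      acc += w * (1.0 + P[s] + (m.wc - 1.0) * win);
    }
    E[e] = acc;
    P[e] = P[e - 1] + acc;
  }
  if (Efwd) *Efwd = E;
  if (Pfwd) *Pfwd = P;
  return 1.0 + P[m.L];
}

// Backward DP: D[s] = weight of suffix configurations whose first molecule
// starts exactly at s; S[s] = sum_{s' >= s} D[s'].
void branch_backward(const Model& m, const double* conc, bool on,
                     std::vector<double>& D, std::vector<double>& S) {
  D.assign(m.L + 1, 0.0);
  S.assign(m.L + 2, 0.0);
  for (int s = m.L - 1; s >= 0; --s) {
    double acc = 0.0;
    for (int t = 0; t < m.nsp; ++t) {
      double w = conc[t] * m.invkd[t][s];
      if (w <= 0.0) continue;
      if (on) {
        double f = m.onfac[t][s];
        if (f == 0.0) continue;
        w *= f;
      }
      int e = s + m.len[t];
      if (e > m.L) continue;
      int hi = std::min(m.L, e + m.dc);
      double win = S[e] - S[hi + 1];
      acc += w * (1.0 + S[e] + (m.wc - 1.0) * win);
    }
    D[s] = acc;
    S[s] = S[s + 1] + acc;
  }
}

double pon_model(const Model& m, double c1, double c2, double c3) {
  double conc[3] = {c1, c2, c3};
  double zoff = branch_Z(m, conc, false);
  double zon = m.qR * branch_Z(m, conc, true);
  return zon / (zon + zoff);
}

// ---- steady state ------------------------------------------------------
// g(c) = cmax * P_on(c) - c; the ODE flow from c_init converges to the
// first root of g encountered in the direction of g(c_init). March
// geometrically to bracket that root, then bisect + secant-polish.
double steady_from(const Model& m, double c1, double c2, double c_init,
                   double cmax, double eps_ss) {
  auto g = [&](double c) { return cmax * pon_model(m, c1, c2, c) - c; };
  double c0 = std::min(std::max(c_init, 0.0), cmax);
  double g0 = g(c0);
  if (std::fabs(g0) < 1e-9 * std::max(1.0, c0)) return c0;
  double lo, hi, glo, ghi;
  bool up = g0 > 0.0;
  double step = std::max(0.5 * eps_ss, 1e-4), prev = c0, gprev = g0;
  for (;;) {
    double nxt = up ? prev + step : prev - step;
    if (up && nxt >= cmax) nxt = cmax;
    if (!up && nxt <= 0.0) nxt = 0.0;
    double gn = g(nxt);
    if ((up && gn <= 0.0) || (!up && gn >= 0.0)) {
      lo = up ? prev : nxt; glo = up ? gprev : gn;
      hi = up ? nxt : prev; ghi = up ? gn : gprev;
      break;
    }
    if (nxt == cmax || nxt == 0.0) return nxt; // boundary fixed point
    // grow the step geometrically but cap it so that narrow attractor
    // basins are not stepped over (the flow must settle on the FIRST
    // stable fixed point in its direction of travel)
    prev = nxt; gprev = gn; step = std::min(step * 1.8, cmax / 64.0);
  }
  // bisection: g(lo) > 0 > g(hi)
  for (int i = 0; i < 30 && hi - lo > 1e-3; ++i) {
    double mid = 0.5 * (lo + hi), gm = g(mid);
    if (gm > 0.0) { lo = mid; glo = gm; } else { hi = mid; ghi = gm; }
  }
  // secant polish within the bracket
  double a = lo, b = hi, ga = glo, gb = ghi, c = 0.5 * (a + b);
  for (int i = 0; i < 12; ++i) {
    double denom = gb - ga;
    c = (std::fabs(denom) > 0.0) ? (a - ga * (b - a) / denom) : 0.5 * (a + b);
    if (!(c > a && c < b)) c = 0.5 * (a + b);
    double gc = g(c);
    if (std::fabs(gc) < 1e-12 * std::max(1.0, c)) return c;
    if (gc > 0.0) { a = c; ga = gc; } else { b = c; gb = gc; }
    if (b - a < 1e-10 * std::max(1.0, b)) break;
  }
  return 0.5 * (a + b);
}

// ---- ODE integration (Cash-Karp RK45, 1-D) -----------------------------
struct StepResult { double c; double err; };

StepResult ck_step(const Model& m, double c1, double c2, double c, double h,
                   double beta, double mu) {
  auto f = [&](double x) {
    x = std::max(x, 0.0);
    return beta * pon_model(m, c1, c2, x) - mu * x;
  };
  const double b21 = 1.0 / 5.0;
  const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
               b54 = 35.0 / 27.0;
  const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
               b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
               b65 = 253.0 / 4096.0;
  const double c1w = 37.0 / 378.0, c3w = 250.0 / 621.0, c4w = 125.0 / 594.0,
               c6w = 512.0 / 1771.0;
  const double d1 = 2825.0 / 27648.0, d3 = 18575.0 / 48384.0,
               d4 = 13525.0 / 55296.0, d5 = 277.0 / 14336.0, d6 = 1.0 / 4.0;
  double k1 = f(c);
  double k2 = f(c + h * b21 * k1);
  double k3 = f(c + h * (b31 * k1 + b32 * k2));
  double k4 = f(c + h * (b41 * k1 + b42 * k2 + b43 * k3));
  double k5 = f(c + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4));
  double k6 = f(c + h * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 + b65 * k5));
  double c5 = c + h * (c1w * k1 + c3w * k3 + c4w * k4 + c6w * k6);
  double c4o = c + h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6);
  StepResult r;
  r.c = c5;
  r.err = std::fabs(c5 - c4o);
  return r;
}

} // namespace

// [[Rcpp::export(name = ".partition_cpp")]]
List partition_cpp(List model, NumericVector conc) {
  Model m = parse_model(model);
  if (conc.size() != m.nsp) stop("need one concentration per TF species");
  for (int i = 0; i < conc.size(); ++i)
    if (conc[i] < 0 || !R_finite(conc[i])) stop("concentrations must be finite and >= 0");
  double cc[3] = {conc[0], conc[1], conc[2]};
  double zoff = branch_Z(m, cc, false);
  double zon = m.qR * branch_Z(m, cc, true);
  return List::create(_["Z_on"] = zon, _["Z_off"] = zoff);
}

// [[Rcpp::export(name = ".pon_cpp")]]
double pon_cpp(List model, NumericVector conc) {
  Model m = parse_model(model);
  for (int i = 0; i < conc.size(); ++i)
    if (conc[i] < 0 || !R_finite(conc[i])) stop("concentrations must be finite and >= 0");
  return pon_model(m, conc[0], conc[1], conc[2]);
}

// [[Rcpp::export(name = ".pon_vec_cpp")]]
NumericVector pon_vec_cpp(List model, double c1, double c2, NumericVector c3) {
  Model m = parse_model(model);
  NumericVector out(c3.size());
  for (int i = 0; i < c3.size(); ++i) out[i] = pon_model(m, c1, c2, c3[i]);
  return out;
}

// Per-site equilibrium occupancies of every species, plus P_on.
// [[Rcpp::export(name = ".occupancy_cpp")]]
List occupancy_cpp(List model, NumericVector conc) {
  Model m = parse_model(model);
  double cc[3] = {conc[0], conc[1], conc[2]};
  std::vector<double> Eoff, Poff, Eon, Pon_;
  double zoff = branch_Z(m, cc, false, &Eoff, &Poff);
  double zon = branch_Z(m, cc, true, &Eon, &Pon_);
  std::vector<double> Doff, Soff, Don, Son;
  branch_backward(m, cc, false, Doff, Soff);
  branch_backward(m, cc, true, Don, Son);
  double Z = zoff + m.qR * zon;
  List out(m.nsp);
  for (int t = 0; t < m.nsp; ++t) {
    NumericVector occ(m.L, 0.0);
    for (int s = 0; s + m.len[t] <= m.L; ++s) {
      double w = cc[t] * m.invkd[t][s];
      if (w <= 0.0) continue;
      int e = s + m.len[t];
      // prefix factor: 1 + plain sum + cooperative window
      int lo = s - m.dc - 1;
      double cof = 1.0 + Poff[s] +
                   (m.wc - 1.0) * (Poff[s] - (lo >= 0 ? Poff[lo] : 0.0));
      int hi = std::min(m.L, e + m.dc);
      double cbf = 1.0 + Soff[e] + (m.wc - 1.0) * (Soff[e] - Soff[hi + 1]);
      double num = w * cof * cbf;
      double fon = m.onfac[t][s];
      if (fon > 0.0) {
        double con = 1.0 + Pon_[s] +
                     (m.wc - 1.0) * (Pon_[s] - (lo >= 0 ? Pon_[lo] : 0.0));
        double cbn = 1.0 + Son[e] + (m.wc - 1.0) * (Son[e] - Son[hi + 1]);
        num += m.qR * w * fon * con * cbn;
      }
      occ[s] = num / Z;
    }
    out[t] = occ;
  }
  out.attr("p_on") = m.qR * zon / Z;
  return out;
}

// [[Rcpp::export(name = ".steady_state_cpp")]]
double steady_state_cpp(List model, double c1, double c2, double c3_init,
                        double beta, double mu, double eps_ss) {
  Model m = parse_model(model);
  double cmax = beta / mu;
  return steady_from(m, c1, c2, c3_init, cmax, eps_ss);
}

// E_RF core: steady states from both initial conditions at every grid point,
// squared deviations from the goal plus the bistability penalty.
// [[Rcpp::export(name = ".score_gate_cpp")]]
List score_gate_cpp(List model, NumericMatrix grid, NumericVector goals,
                    double beta, double mu, double eps_ss, double c0) {
  Model m = parse_model(model);
  double cmax = beta / mu;
  int n = grid.nrow();
  NumericVector lo(n), hi(n);
  double e_rf = 0.0, pen = 0.0;
  for (int i = 0; i < n; ++i) {
    double c1 = grid(i, 0), c2 = grid(i, 1);
    double ssl = steady_from(m, c1, c2, 0.0, cmax, eps_ss);
    double ssh = steady_from(m, c1, c2, cmax, cmax, eps_ss);
    lo[i] = ssl; hi[i] = ssh;
    double d = ssl - goals[i];
    e_rf += d * d / (c0 * c0);
    double b = ssh - ssl;
    if (std::fabs(b) > eps_ss) pen += b * b / (c0 * c0);
  }
  return List::create(_["e_rf"] = e_rf, _["penalty"] = pen,
                      _["ss_low"] = lo, _["ss_high"] = hi);
}

// First passage time into the band |c3 - c3_star| < eps_rt, integrating
// dc3/dt = beta * P_on - mu * c3 with adaptive RK45.
// [[Rcpp::export(name = ".response_time_cpp")]]
double response_time_cpp(List model, double c1, double c2, double c3_init,
                         double c3_star, double beta, double mu,
                         double eps_rt, double t_max) {
  Model m = parse_model(model);
  double c = std::max(c3_init, 0.0), t = 0.0;
  if (std::fabs(c - c3_star) < eps_rt) return 0.0;
  double h = 0.01 / mu;
  const double rtol = 1e-8, atol = 1e-8;
  while (t < t_max) {
    StepResult r = ck_step(m, c1, c2, c, h, beta, mu);
    double sc = atol + rtol * std::max(std::fabs(c), std::fabs(r.c));
    if (r.err > sc) { // reject
      h *= std::max(0.2, 0.9 * std::pow(sc / r.err, 0.25));
      continue;
    }
    if (std::fabs(r.c - c3_star) < eps_rt) {
      // crossing inside (t, t+h]: bisect the step length
      double hl = 0.0, hh = h;
      for (int i = 0; i < 40; ++i) {
        double hm = 0.5 * (hl + hh);
        StepResult rm = ck_step(m, c1, c2, c, hm, beta, mu);
        if (std::fabs(rm.c - c3_star) < eps_rt) hh = hm; else hl = hm;
        if (hh - hl < 1e-10 * std::max(1.0, hh)) break;
      }
      return t + hh;
    }
    t += h; c = r.c;
    h *= std::min(5.0, 0.9 * std::pow(sc / std::max(r.err, 1e-300), 0.2));
    if (t + h > t_max) h = t_max - t;
  }
  return NA_REAL; // did not reach the band
}

// Sum over amino-acid/base contact energies for every start position.
// tf: integers 1..20, cis: integers 1..4, eps: 20 x 4 matrix (kT).
// [[Rcpp::export(name = ".scan_energies_cpp")]]
NumericVector scan_energies_cpp(IntegerVector tf, IntegerVector cis,
                                NumericMatrix eps) {
  int lt = tf.size(), L = cis.size();
  if (L < lt) stop("cis region shorter than the TF binding domain");
  int n = L - lt + 1;
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    double e = 0.0;
    for (int i = 0; i < lt; ++i) e += eps(tf[i] - 1, cis[s + i] - 1);
    out[s] = e;
  }
  return out;
}
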