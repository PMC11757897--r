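// Steady-state residual kernel for microvascular network flow.
//
// Unknown vector layout: [interior nodal pressures, then one haematocrit per
// non-inlet vessel, in vessel order]. Flows are eliminated through
// Poiseuille's law and normalised by the total network inflow, so all
// residual entries are dimensionless and invariant under uniform rescaling
// of flows, plasma viscosity, reference length and boundary-pressure span.
//
// mode 0: full network equations F (flow conservation at interior nodes;
//         RBC conservation at convergences; splitting rule at bifurcations).
// mode 1: starting system G for the homotopy -- viscosity frozen at
//         mu(hfreeze, D) and every haematocrit equation replaced by
//         H - hfreeze = 0. Linear in the pressures, with a unique solution.

#include <Rcpp.h>
using namespace Rcpp;

static const double EPS_Q = 1e-14;

// in-vivo apparent viscosity, haematocrit-dependent part evaluated at
// runtime; diameter-only terms are precompiled in R (compile_network)
static inline double viscosity(double H, double mu45, double C,
                               double wall, double denom055, double mu_p) {
  double Heff = H;
  if (Heff > 0.995) Heff = 0.995;
  if (Heff < -0.5) Heff = -0.5;
  double corr = (std::pow(1.0 - Heff, C) - 1.0) / denom055;
  return mu_p * (1.0 + (mu45 - 1.0) * corr * wall) * wall;
}

static inline double psi_pries(double r, double Hp, double Dp,
                               double logDd, double logDs, double X0) {
  if (r < X0) return 0.0;
  if (r > 1.0 - X0) return 1.0;
  double Hpc = Hp;
  if (Hpc < 0.0) Hpc = 0.0;
  if (Hpc > 0.9999) Hpc = 0.9999;
  double A = -6.96 / Dp * (logDd - logDs);
  double rho = 1.0 + 6.98 * (1.0 - Hpc) / Dp;
  double ra = r - X0;      if (ra < 0.0) ra = 0.0;
  double rb = 1.0 - r - X0; if (rb < 0.0) rb = 0.0;
  double a = std::exp(A) * std::pow(ra, rho);
  double b = std::pow(rb, rho);
  return a / (a + b);
}

NumericVector residual_kernel(NumericVector x, List cn, int mode,
                              double hfreeze) {
  IntegerVector kind = cn["kind"], from0 = cn["from0"], to0 = cn["to0"],
                h_idx = cn["h_idx"], p_idx = cn["p_idx"], int0 = cn["int0"];
  NumericVector p_bound = cn["p_bound"], len = cn["len"], diam = cn["diam"],
                hfix = cn["hfix"], mu45v = cn["mu45v"], Cv = cn["Cv"],
                wallv = cn["wallv"], denomv = cn["denomv"], rpre = cn["rpre"],
                x0v = cn["x0v"], logD = cn["logD"];
  IntegerMatrix incid = cn["incid"], sgn = cn["sgn"];
  double mu_p = as<double>(cn["mu_p"]);
  int rule = as<int>(cn["rule_code"]);

  const int n_nodes = kind.size();
  const int m = from0.size();
  const int n_int = int0.size();
  const int n_unknown = as<int>(cn["n_unknown"]);

  // nodal pressures
  std::vector<double> P(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    P[v] = (p_idx[v] >= 0) ? x[p_idx[v]] : p_bound[v];

  // vessel haematocrits
  std::vector<double> H(m);
  for (int e = 0; e < m; ++e)
    H[e] = (h_idx[e] >= 0) ? x[n_int + h_idx[e]] : hfix[e];

  // signed flows (reference orientation from0 -> to0)
  std::vector<double> Q(m);
  double Qin = 0.0, Qabsmax = 0.0;
  for (int e = 0; e < m; ++e) {
    double Hv = (mode == 1) ? hfreeze : H[e];
    double mu = viscosity(Hv, mu45v[e], Cv[e], wallv[e], denomv[e], mu_p);
    Q[e] = (P[from0[e]] - P[to0[e]]) / (rpre[e] * mu);
    if (h_idx[e] < 0) Qin += Q[e];  // inlet vessels point into the network
    double a = std::fabs(Q[e]);
    if (a > Qabsmax) Qabsmax = a;
  }
  // normalise by the inflow only when it dominates round-off; otherwise use
  // the largest flow magnitude so noise is never amplified
  double floor_q = (1e-8 * Qabsmax > EPS_Q) ? 1e-8 * Qabsmax : EPS_Q;
  double scale = (Qin > floor_q) ? Qin : (Qabsmax > EPS_Q ? Qabsmax : 1.0);
  for (int e = 0; e < m; ++e) Q[e] /= scale;

  // interior-node column lookup
  std::vector<int> int_col(n_nodes, -1);
  for (int j = 0; j < n_int; ++j) int_col[int0[j]] = j;

  NumericVector res(n_unknown);

  // flow conservation at interior nodes
  for (int j = 0; j < n_int; ++j) {
    double s = 0.0;
    for (int k = 0; k < 3; ++k) s += sgn(k, j) * Q[incid(k, j)];
    res[j] = s;
  }

  // haematocrit equations, one per non-inlet vessel
  for (int e = 0; e < m; ++e) {
    if (h_idx[e] < 0) continue;
    int row = n_int + h_idx[e];
    if (mode == 1) { res[row] = H[e] - hfreeze; continue; }

    int u = (Q[e] >= 0.0) ? from0[e] : to0[e];  // upstream endpoint
    int j = int_col[u];
    if (j < 0) {
      // reversed flow out of a boundary node (non-physical intermediate
      // state): fall back to RBC conservation at the interior endpoint
      int w = (u == from0[e]) ? to0[e] : from0[e];
      j = int_col[w];
      if (j < 0) { res[row] = H[e]; continue; }
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += sgn(k, j) * Q[incid(k, j)] * H[incid(k, j)];
      res[row] = s;
      continue;
    }

    // classify junction u from current flow signs
    int nin = 0, nout = 0, parent = -1, sib = -1;
    for (int k = 0; k < 3; ++k) {
      int ek = incid(k, j);
      double f = sgn(k, j) * Q[ek];  // positive = into node u
      if (f > EPS_Q) { ++nin; parent = ek; }
      else if (f < -EPS_Q) { ++nout; if (ek != e) sib = ek; }
    }

    if (nin == 1 && nout == 2 && parent >= 0 && sib >= 0 &&
        std::fabs(Q[parent]) > EPS_Q) {
      // bifurcation: splitting rule for daughter e
      double qp = std::fabs(Q[parent]);
      double qd = std::fabs(Q[e]);
      double r = qd / qp;
      if (r < 0.0) r = 0.0;
      if (r > 1.0) r = 1.0;
      double Hp = H[parent];
      double p;
      if (rule == 1) p = r;
      else p = psi_pries(r, Hp, diam[parent], logD[e], logD[sib],
                         x0v[parent]);
      res[row] = p * qp * Hp - qd * H[e];
    } else {
      // convergence (2 in / 1 out) or degenerate configuration:
      // conservative product form of RBC conservation at u
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        int ek = incid(k, j);
        s += sgn(k, j) * Q[ek] * H[ek];
      }
      res[row] = s;
    }
  }
  return res;
}

// raw signed flows for a given state (reference orientation)
NumericVector flows_kernel(NumericVector x, List cn, int mode,
                           double hfreeze) {
  IntegerVector from0 = cn["from0"], to0 = cn["to0"], h_idx = cn["h_idx"],
                p_idx = cn["p_idx"];
  NumericVector p_bound = cn["p_bound"], hfix = cn["hfix"],
                mu45v = cn["mu45v"], Cv = cn["Cv"], wallv = cn["wallv"],
                denomv = cn["denomv"], rpre = cn["rpre"];
  double mu_p = as<double>(cn["mu_p"]);
  int n_int = as<IntegerVector>(cn["int0"]).size();
  const int m = from0.size();
  const int n_nodes = p_bound.size();

  std::vector<double> P(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    P[v] = (p_idx[v] >= 0) ? x[p_idx[v]] : p_bound[v];

  NumericVector Q(m);
  double Qin = 0.0;
  for (int e = 0; e < m; ++e) {
    double Hv = (mode == 1) ? hfreeze
                            : ((h_idx[e] >= 0) ? x[n_int + h_idx[e]] : hfix[e]);
    double mu = viscosity(Hv, mu45v[e], Cv[e], wallv[e], denomv[e], mu_p);
    Q[e] = (P[from0[e]] - P[to0[e]]) / (rpre[e] * mu);
    if (h_idx[e] < 0) Qin += Q[e];
  }
  Q.attr("Qin") = Qin;
  return Q;
}

// ---- .Call entry points ----------------------------------------------------

extern "C" SEXP _hemonet_residual_kernel(SEXP xSEXP, SEXP cnSEXP,
                                         SEXP modeSEXP, SEXP hfreezeSEXP) {
  BEGIN_RCPP
  Rcpp::RObject rcpp_result_gen;
  rcpp_result_gen = Rcpp::wrap(residual_kernel(
      Rcpp::as<NumericVector>(xSEXP), Rcpp::as<List>(cnSEXP),
      Rcpp::as<int>(modeSEXP), Rcpp::as<double>(hfreezeSEXP)));
  return rcpp_result_gen;
  END_RCPP
}

extern "C" SEXP _hemonet_flows_kernel(SEXP xSEXP, SEXP cnSEXP,
                                      SEXP modeSEXP, SEXP hfreezeSEXP) {
  BEGIN_RCPP
  Rcpp::RObject rcpp_result_gen;
  rcpp_result_gen = Rcpp::wrap(flows_kernel(
      Rcpp::as<NumericVector>(xSEXP), Rcpp::as<List>(cnSEXP),
      Rcpp::as<int>(modeSEXP), Rcpp::as<double>(hfreezeSEXP)));
  return rcpp_result_gen;
  END_RCPP
}
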