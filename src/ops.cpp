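#include "core.h"
using namespace Rcpp;

// Exported scalar/vector kernels backing the R-level operations. The session
// engine (session.cpp) calls the same inline functions from core.h.

// [[Rcpp::export]]
NumericVector cpp_integrate_unit(NumericVector a, NumericVector I, double dt,
                                 double tau) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ad::integrate_unit(a[i], I[i % I.size()], dt, tau);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_squash(NumericVector a, double eps) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::squash(a[i], eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_effective_weight(NumericVector w, double lambda, bool d1) {
  int n = w.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::effective_weight(w[i], lambda, d1);
  return out;
}

// [[Rcpp::export]]
double cpp_update_prediction(double y, bool flash, bool seen_first, double k) {
  return ad::update_prediction(y, flash, seen_first, k);
}

// [[Rcpp::export]]
NumericVector cpp_novelty_salience(NumericVector y_star) {
  int n = y_star.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::novelty_salience(y_star[i]);
  return out;
}

// [[Rcpp::export]]
double cpp_sc_response(double y_f, double y_star) {
  return ad::sc_response(y_f, y_star);
}

// [[Rcpp::export]]
double cpp_cancel_signal(double y_f, double y_star) {
  return ad::cancel_signal(y_f, y_star);
}

// [[Rcpp::export]]
double cpp_snc_input(double y_sc, double y_cancel, double a_plus,
                     double a_minus) {
  return ad::snc_input(y_sc, y_cancel, a_plus, a_minus);
}

// [[Rcpp::export]]
NumericVector cpp_snc_output(NumericVector a_snc) {
  int n = a_snc.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::snc_output(a_snc[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_triangular_pulse(NumericVector t, double t_event,
                                   double width, double amplitude) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ad::triangular_pulse(t[i], t_event, width, amplitude);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_alpha_mix(NumericVector d) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::alpha_mix(d[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_blend_coefficient(double A_hi, double A_lo,
                                    NumericVector d) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::blend_coefficient(A_hi, A_lo, d[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_c_bcm(NumericVector d, bool d1, List coeffs,
                        double tau_ratio, double k_c) {
  ad::PlasticityCoefficients A = ad::coeffs_from_list(coeffs);
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ad::c_bcm(d[i], d1, A, tau_ratio, k_c);
  return out;
}

// [[Rcpp::export]]
double cpp_weight_update(double w, double x, double y, double theta,
                         double eta, double dt, double w_min, double w_max) {
  return ad::weight_update(w, x, y, theta, eta, dt, w_min, w_max);
}

// [[Rcpp::export]]
double cpp_update_ysq(double tracker, double y, double dt, double ysq_tau) {
  return ad::update_ysq(tracker, y, dt, ysq_tau);
}

// ---------------------------------------------------------------------------
// List <-> struct conversions
// ---------------------------------------------------------------------------

namespace ad {

static double num(const List& l, const char* name) {
  if (!l.containsElementNamed(name))
    stop("missing network parameter '%s'", name);
  return as<double>(l[name]);
}

NetParams net_params_from_list(const List& cfg) {
  NetParams p;
  p.dt = num(cfg, "dt");
  p.tau = num(cfg, "tau");
  p.eps_ssc = num(cfg, "eps_ssc");
  p.eps_mc = num(cfg, "eps_mc");
  p.eps_str = num(cfg, "eps_str");
  p.eps_stn = num(cfg, "eps_stn");
  p.eps_gpe = num(cfg, "eps_gpe");
  p.eps_gpi = num(cfg, "eps_gpi");
  p.eps_vl = num(cfg, "eps_vl");
  p.eps_trn = num(cfg, "eps_trn");
  p.eps_bs = num(cfg, "eps_bs");
  p.w_sm = num(cfg, "w_sm");
  p.w_vm = num(cfg, "w_vm");
  p.w_mm = num(cfg, "w_mm");
  p.w_cstn = num(cfg, "w_cstn");
  p.w_gstn = num(cfg, "w_gstn");
  p.w_stn_gpi = num(cfg, "w_stn_gpi");
  p.w_stn_gpe = num(cfg, "w_stn_gpe");
  p.w_d1_gpi = num(cfg, "w_d1_gpi");
  p.w_d2_gpe = num(cfg, "w_d2_gpe");
  p.w_gpe_gpi = num(cfg, "w_gpe_gpi");
  p.w_cv = num(cfg, "w_cv");
  p.w_gv = num(cfg, "w_gv");
  p.w_tv = num(cfg, "w_tv");
  p.w_td = num(cfg, "w_td");
  p.w_ct = num(cfg, "w_ct");
  p.w_vt = num(cfg, "w_vt");
  p.w_gt = num(cfg, "w_gt");
  p.w_mb = num(cfg, "w_mb");
  p.w_gb = num(cfg, "w_gb");
  p.lambda = num(cfg, "lambda");
  p.phi = num(cfg, "phi");
  p.noise_sd = num(cfg, "noise_sd");
  if (p.dt <= 0 || p.dt > p.tau)
    stop("integration-stability error: require 0 < dt <= tau");
  if (p.lambda < 0 || p.lambda >= 1) stop("lambda must be in [0, 1)");
  return p;
}

CorticoStriatalWeights weights_from_list(const List& w) {
  CorticoStriatalWeights W;
  NumericVector md1 = w["m_d1"], sd1 = w["s_d1"], md2 = w["m_d2"],
                sd2 = w["s_d2"];
  if (md1.size() != NCHAN || sd1.size() != NCHAN || md2.size() != NCHAN ||
      sd2.size() != NCHAN)
    stop("cortico-striatal weight vectors must have length 3");
  for (int i = 0; i < NCHAN; ++i) {
    W.m_d1[i] = md1[i];
    W.s_d1[i] = sd1[i];
    W.m_d2[i] = md2[i];
    W.s_d2[i] = sd2[i];
    if (W.m_d1[i] < 0 || W.s_d1[i] < 0 || W.m_d2[i] < 0 || W.s_d2[i] < 0)
      stop("cortico-striatal weights must be non-negative");
  }
  return W;
}

List weights_to_list(const CorticoStriatalWeights& w) {
  return List::create(
      _["m_d1"] = NumericVector(w.m_d1, w.m_d1 + NCHAN),
      _["s_d1"] = NumericVector(w.s_d1, w.s_d1 + NCHAN),
      _["m_d2"] = NumericVector(w.m_d2, w.m_d2 + NCHAN),
      _["s_d2"] = NumericVector(w.s_d2, w.s_d2 + NCHAN));
}

static void pop_from_list(const List& st, const char* name, Pop& p) {
  List pl = st[name];
  NumericVector a = pl["a"], y = pl["y"];
  for (int i = 0; i < NCHAN; ++i) {
    p.a[i] = a[i];
    p.y[i] = y[i];
  }
}

static List pop_to_list(const Pop& p) {
  return List::create(_["a"] = NumericVector(p.a, p.a + NCHAN),
                      _["y"] = NumericVector(p.y, p.y + NCHAN));
}

NetState net_state_from_list(const List& st) {
  NetState n;
  pop_from_list(st, "ssc", n.ssc);
  pop_from_list(st, "mc", n.mc);
  pop_from_list(st, "d1", n.d1);
  pop_from_list(st, "d2", n.d2);
  pop_from_list(st, "stn", n.stn);
  pop_from_list(st, "gpe", n.gpe);
  pop_from_list(st, "gpi", n.gpi);
  pop_from_list(st, "vl", n.vl);
  pop_from_list(st, "trn", n.trn);
  pop_from_list(st, "bs", n.bs);
  return n;
}

List net_state_to_list(const NetState& n) {
  return List::create(
      _["ssc"] = pop_to_list(n.ssc), _["mc"] = pop_to_list(n.mc),
      _["d1"] = pop_to_list(n.d1), _["d2"] = pop_to_list(n.d2),
      _["stn"] = pop_to_list(n.stn), _["gpe"] = pop_to_list(n.gpe),
      _["gpi"] = pop_to_list(n.gpi), _["vl"] = pop_to_list(n.vl),
      _["trn"] = pop_to_list(n.trn), _["bs"] = pop_to_list(n.bs));
}

PlasticityCoefficients coeffs_from_list(const List& cfg) {
  PlasticityCoefficients A;
  A.d1_hi_p = num(cfg, "A_d1_hi_plus");
  A.d1_hi_m = num(cfg, "A_d1_hi_minus");
  A.d1_lo_p = num(cfg, "A_d1_lo_plus");
  A.d1_lo_m = num(cfg, "A_d1_lo_minus");
  A.d2_hi_p = num(cfg, "A_d2_hi_plus");
  A.d2_hi_m = num(cfg, "A_d2_hi_minus");
  A.d2_lo_p = num(cfg, "A_d2_lo_plus");
  A.d2_lo_m = num(cfg, "A_d2_lo_minus");
  return A;
}

}  // namespace ad
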