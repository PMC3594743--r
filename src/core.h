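#ifndef ACTIONDISCOVERY_CORE_H
#define ACTIONDISCOVERY_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <algorithm>

namespace ad {

// ---------------------------------------------------------------------------
// Elementary neural unit operations
// ---------------------------------------------------------------------------

// One forward-Euler step of tau * da/dt = -a + I.
inline double integrate_unit(double a, double I, double dt, double tau) {
  return a + (dt / tau) * (-a + I);
}

// Piecewise-linear squashing: 0 below eps, unit slope, saturation at 1.
inline double squash(double a, double eps) {
  if (a <= eps) return 0.0;
  if (a >= 1.0 + eps) return 1.0;
  return a - eps;
}

// Tonic dopamine scales cortico-striatal transmission: D1 facilitated by
// (1 + lambda), D2 attenuated by (1 - lambda).
inline double effective_weight(double w, double lambda, bool d1) {
  return d1 ? w * (1.0 + lambda) : w * (1.0 - lambda);
}

// ---------------------------------------------------------------------------
// Prediction of the phasic outcome (latent y), novelty salience
// ---------------------------------------------------------------------------

// Recursive prediction update at an interaction event. flash: outcome
// delivered; first ever flash jumps the latent prediction to 0.2. Omission
// decays a non-zero prediction by k; a zero prediction is untouched.
inline double update_prediction(double y, bool flash, bool seen_first,
                                double k) {
  if (flash) {
    if (!seen_first) return 0.2;
    return 1.0 - k * (1.0 - y);
  }
  if (y > 0.0) return k * y;
  return y;
}

// Novelty salience tent map: maximal (0.5) at the least predictable outcome.
inline double novelty_salience(double y_star) {
  return 0.5 - std::fabs(y_star - 0.5);
}

// ---------------------------------------------------------------------------
// Phasic dopamine: sensory prediction error via SC and canceling pathways
// ---------------------------------------------------------------------------

inline double pos(double x) { return x > 0.0 ? x : 0.0; }

inline double sc_response(double y_f, double y_star) { return pos(y_f - y_star); }
inline double cancel_signal(double y_f, double y_star) { return pos(y_star - y_f); }

inline double snc_input(double y_sc, double y_cancel, double a_plus,
                        double a_minus) {
  return a_plus * y_sc - a_minus * y_cancel;
}

// Unnormalized SNc read-out: rectified at -0.2, resting level 0.2, no
// saturation (required for interpreting the output as a dopamine level).
inline double snc_output(double a_snc) { return pos(a_snc + 0.2); }

// Triangular pulse of given width and amplitude, peak at the window center.
inline double triangular_pulse(double t, double t_event, double width,
                               double amplitude) {
  double s = t - t_event;
  if (s < 0.0 || s > width) return 0.0;
  return amplitude * (1.0 - std::fabs(2.0 * s / width - 1.0));
}

// ---------------------------------------------------------------------------
// Dopamine-blended BCM plasticity
// ---------------------------------------------------------------------------

// Monotonic saturating dopamine mixing function.
inline double alpha_mix(double d) { return 4.0 * d / (1.0 + 4.0 * d); }

inline double blend_coefficient(double A_hi, double A_lo, double d) {
  double a = alpha_mix(d);
  return a * A_hi + (1.0 - a) * A_lo;
}

struct PlasticityCoefficients {
  double d1_hi_p, d1_hi_m;  // A+^{D1(hi)}, A-^{D1(hi)}
  double d1_lo_p, d1_lo_m;
  double d2_hi_p, d2_hi_m;
  double d2_lo_p, d2_lo_m;
};

// C_BCM(d) = -(A-(d) tau- + A+(d) tau+) / (A3 tau+ tau_y). With tau+ = tau-
// the time constants collapse and 1/(A3 tau_y) is the lumped positive scale
// k_c, giving C_BCM = -k_c (A+(d) + A-(d)).
inline double c_bcm(double d, bool d1, const PlasticityCoefficients& A,
                    double tau_ratio, double k_c) {
  double Ap, Am;
  if (d1) {
    Ap = blend_coefficient(A.d1_hi_p, A.d1_lo_p, d);
    Am = blend_coefficient(A.d1_hi_m, A.d1_lo_m, d);
  } else {
    Ap = blend_coefficient(A.d2_hi_p, A.d2_lo_p, d);
    Am = blend_coefficient(A.d2_hi_m, A.d2_lo_m, d);
  }
  return -k_c * (Am * tau_ratio + Ap);
}

inline double theta_bcm(double ysq, double c) { return ysq * c; }

// BCM weight increment with hard bounds.
inline double weight_update(double w, double x, double y, double theta,
                            double eta, double dt, double w_min,
                            double w_max) {
  double w2 = w + dt * eta * y * (y - theta) * x;
  return std::min(w_max, std::max(w_min, w2));
}

// Exponential moving average of y^2.
inline double update_ysq(double tracker, double y, double dt, double ysq_tau) {
  return tracker + (dt / ysq_tau) * (y * y - tracker);
}

// ---------------------------------------------------------------------------
// Network state and parameters (3 action channels)
// ---------------------------------------------------------------------------

const int NCHAN = 3;
const int CH_EXPLORE = 0;
const int CH_RED = 1;
const int CH_WHITE = 2;

struct NetParams {
  double dt, tau;
  // per-population output thresholds
  double eps_ssc, eps_mc, eps_str, eps_stn, eps_gpe, eps_gpi, eps_vl,
      eps_trn, eps_bs;
  // gains
  double w_sm;      // sensory cortex -> motor cortex
  double w_vm;      // VL -> motor cortex
  double w_mm;      // motor cortex recurrent (< 1)
  double w_cstn;    // motor cortex -> STN
  double w_gstn;    // GPe -> STN
  double w_stn_gpi; // diffuse STN -> GPi/SNr (summed over channels)
  double w_stn_gpe; // diffuse STN -> GPe
  double w_d1_gpi;  // D1 striatum -> GPi/SNr
  double w_d2_gpe;  // D2 striatum -> GPe
  double w_gpe_gpi; // GPe -> GPi/SNr
  double w_cv;      // motor cortex -> VL
  double w_gv;      // GPi/SNr -> VL
  double w_tv;      // TRN -> VL (same channel)
  double w_td;      // TRN -> VL (other channels)
  double w_ct;      // motor cortex -> TRN
  double w_vt;      // VL -> TRN
  double w_gt;      // GPi/SNr -> TRN
  double w_mb;      // motor cortex -> brainstem
  double w_gb;      // GPi/SNr -> brainstem
  double lambda;    // tonic dopamine level
  double phi;       // selection threshold on brainstem output
  double noise_sd;  // per-step Gaussian noise on sensory cortical input
};

struct Pop {
  double a[NCHAN];
  double y[NCHAN];
};

struct NetState {
  Pop ssc, mc, d1, d2, stn, gpe, gpi, vl, trn, bs;
};

struct CorticoStriatalWeights {
  double m_d1[NCHAN], s_d1[NCHAN];  // motor / sensory weights to D1
  double m_d2[NCHAN], s_d2[NCHAN];  // motor / sensory weights to D2
};

inline void net_init(NetState& n) { std::memset(&n, 0, sizeof(NetState)); }

// One Euler step of the full network given per-channel salience input s[3].
// noise[i] is additive input noise for sensory cortex (pass zeros for
// deterministic stepping).
inline void net_step(NetState& n, const double* s, const double* noise,
                     const CorticoStriatalWeights& W, const NetParams& p) {
  double I_ssc[NCHAN], I_mc[NCHAN], I_d1[NCHAN], I_d2[NCHAN], I_stn[NCHAN],
      I_gpe[NCHAN], I_gpi[NCHAN], I_vl[NCHAN], I_trn[NCHAN], I_bs[NCHAN];

  double stn_sum = 0.0, trn_sum = 0.0;
  for (int i = 0; i < NCHAN; ++i) {
    stn_sum += n.stn.y[i];
    trn_sum += n.trn.y[i];
  }

  for (int i = 0; i < NCHAN; ++i) {
    I_ssc[i] = s[i] + noise[i];
    I_mc[i] = p.w_sm * n.ssc.y[i] + p.w_vm * n.vl.y[i] + p.w_mm * n.mc.y[i];
    double ctx_d1 = W.m_d1[i] * n.mc.y[i] + W.s_d1[i] * n.ssc.y[i];
    double ctx_d2 = W.m_d2[i] * n.mc.y[i] + W.s_d2[i] * n.ssc.y[i];
    I_d1[i] = effective_weight(ctx_d1, p.lambda, true);
    I_d2[i] = effective_weight(ctx_d2, p.lambda, false);
    I_stn[i] = p.w_cstn * n.mc.y[i] - p.w_gstn * n.gpe.y[i];
    I_gpe[i] = p.w_stn_gpe * stn_sum - p.w_d2_gpe * n.d2.y[i];
    I_gpi[i] = p.w_stn_gpi * stn_sum - p.w_d1_gpi * n.d1.y[i] -
               p.w_gpe_gpi * n.gpe.y[i];
    I_vl[i] = p.w_cv * n.mc.y[i] - p.w_gv * n.gpi.y[i] -
              p.w_tv * n.trn.y[i] - p.w_td * (trn_sum - n.trn.y[i]);
    I_trn[i] = p.w_ct * n.mc.y[i] + p.w_vt * n.vl.y[i] - p.w_gt * n.gpi.y[i];
    I_bs[i] = p.w_mb * n.mc.y[i] - p.w_gb * n.gpi.y[i];
  }

  for (int i = 0; i < NCHAN; ++i) {
    n.ssc.a[i] = integrate_unit(n.ssc.a[i], I_ssc[i], p.dt, p.tau);
    n.mc.a[i] = integrate_unit(n.mc.a[i], I_mc[i], p.dt, p.tau);
    n.d1.a[i] = integrate_unit(n.d1.a[i], I_d1[i], p.dt, p.tau);
    n.d2.a[i] = integrate_unit(n.d2.a[i], I_d2[i], p.dt, p.tau);
    n.stn.a[i] = integrate_unit(n.stn.a[i], I_stn[i], p.dt, p.tau);
    n.gpe.a[i] = integrate_unit(n.gpe.a[i], I_gpe[i], p.dt, p.tau);
    n.gpi.a[i] = integrate_unit(n.gpi.a[i], I_gpi[i], p.dt, p.tau);
    n.vl.a[i] = integrate_unit(n.vl.a[i], I_vl[i], p.dt, p.tau);
    n.trn.a[i] = integrate_unit(n.trn.a[i], I_trn[i], p.dt, p.tau);
    n.bs.a[i] = integrate_unit(n.bs.a[i], I_bs[i], p.dt, p.tau);

    n.ssc.y[i] = squash(n.ssc.a[i], p.eps_ssc);
    n.mc.y[i] = squash(n.mc.a[i], p.eps_mc);
    n.d1.y[i] = squash(n.d1.a[i], p.eps_str);
    n.d2.y[i] = squash(n.d2.a[i], p.eps_str);
    n.stn.y[i] = squash(n.stn.a[i], p.eps_stn);
    n.gpe.y[i] = squash(n.gpe.a[i], p.eps_gpe);
    n.gpi.y[i] = squash(n.gpi.a[i], p.eps_gpi);
    n.vl.y[i] = squash(n.vl.a[i], p.eps_vl);
    n.trn.y[i] = squash(n.trn.a[i], p.eps_trn);
    n.bs.y[i] = squash(n.bs.a[i], p.eps_bs);
  }
}

// ---------------------------------------------------------------------------
// Conversion helpers (R list <-> structs)
// ---------------------------------------------------------------------------

NetParams net_params_from_list(const Rcpp::List& cfg);
CorticoStriatalWeights weights_from_list(const Rcpp::List& w);
Rcpp::List weights_to_list(const CorticoStriatalWeights& w);
NetState net_state_from_list(const Rcpp::List& st);
Rcpp::List net_state_to_list(const NetState& n);
PlasticityCoefficients coeffs_from_list(const Rcpp::List& cfg);

}  // namespace ad

#endif
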