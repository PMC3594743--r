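#include "core.h"
using namespace Rcpp;

// Network-level stepping exposed to R: used by the selection battery, motor
// weight calibration and unit tests. The full closed-loop engine lives in
// session.cpp and shares ad::net_step().

// [[Rcpp::export]]
List cpp_network_rest() {
  ad::NetState n;
  ad::net_init(n);
  return ad::net_state_to_list(n);
}

// Advance the network n_steps with static salience input. noise_sd = 0 gives
// deterministic dynamics (used by equilibrium tests).
// [[Rcpp::export]]
List cpp_network_run(List state, NumericVector saliences, List weights,
                     List net_cfg, int n_steps, double noise_sd) {
  ad::NetState n = ad::net_state_from_list(state);
  ad::NetParams p = ad::net_params_from_list(net_cfg);
  ad::CorticoStriatalWeights W = ad::weights_from_list(weights);
  if (saliences.size() != ad::NCHAN) stop("saliences must have length 3");
  double s[ad::NCHAN], noise[ad::NCHAN] = {0, 0, 0};
  for (int i = 0; i < ad::NCHAN; ++i) s[i] = saliences[i];
  RNGScope scope;
  for (int t = 0; t < n_steps; ++t) {
    if (noise_sd > 0)
      for (int i = 0; i < ad::NCHAN; ++i) noise[i] = R::rnorm(0.0, noise_sd);
    ad::net_step(n, s, noise, W, p);
    for (int i = 0; i < ad::NCHAN; ++i)
      if (!std::isfinite(n.bs.a[i]))
        stop("non-finite activation: network parameterization error");
  }
  return ad::net_state_to_list(n);
}
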