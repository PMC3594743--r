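#' Dopamine mixing function
#'
#' Monotonic saturating map used to blend the low- and high-dopamine
#' plasticity coefficients: `alpha(d) = 4d / (1 + 4d)`.
#'
#' @param d dopamine level(s), `d >= 0`.
#' @return Mixing value(s) in \[0, 1).
#' @export
#' @examples
#' alpha_mix(c(0, 0.25, 1))  # 0, 0.5, 0.8
alpha_mix <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  cpp_alpha_mix(as.numeric(d))
}

#' Blend plasticity coefficients by dopamine level
#'
#' `A(d) = alpha(d) A_hi + (1 - alpha(d)) A_lo`, applied to each of the four
#' (receptor, timing-sign) coefficient pairs.
#'
#' @param A_hi coefficient at high dopamine.
#' @param A_lo coefficient at low dopamine.
#' @param d dopamine level(s).
#' @return Blended coefficient(s).
#' @export
blend_coefficient <- function(A_hi, A_lo, d) {
  cpp_blend_coefficient(A_hi, A_lo, as.numeric(d))
}

#' BCM threshold factor C_BCM(d)
#'
#' With equal pair time constants the factor reduces to
#' `C_BCM(d) = -k_c (A+(d) + A-(d) * tau_ratio)` where `k_c > 0` lumps the
#' triplet factor and time constants. Its sign structure carries the
#' receptor dichotomy: positive for D1 at low dopamine (favoring LTD),
#' negative for D1 at high dopamine (favoring LTP), and the mirror image
#' for D2.
#'
#' @param d dopamine level(s).
#' @param receptor `"D1"` or `"D2"`.
#' @param coeffs the `plasticity` section of a configuration (or any list
#'   holding the eight `A_*` coefficients plus `tau_ratio`, `k_c`).
#' @return C_BCM value(s).
#' @export
c_bcm <- function(d, receptor = c("D1", "D2"),
                  coeffs = default_config()$plasticity) {
  receptor <- match.arg(receptor)
  cpp_c_bcm(as.numeric(d), receptor == "D1", coeffs,
            coeffs$tau_ratio, coeffs$k_c)
}

#' Sliding BCM threshold
#'
#' `theta_BCM = <y^2> C_BCM(d)`: the postsynaptic-activity tracker scales
#' the dopamine-dependent factor, so high cortical drive amplifies the
#' threshold magnitude proportionally.
#'
#' @param ysq tracked mean-square postsynaptic rate.
#' @param c C_BCM value.
#' @return Threshold value(s).
#' @export
theta_bcm <- function(ysq, c) {
  if (any(ysq < 0)) stop("ysq must be non-negative")
  ysq * c
}

#' BCM weight update
#'
#' One Euler step of the rate-coded rule
#' `dw/dt = eta * y (y - theta) x`, clipped to `[w_min, w_max]`. The update
#' is applied only inside the plasticity window that follows a phasic
#' dopamine event.
#'
#' @param w current weight.
#' @param x presynaptic (cortical) rate.
#' @param y postsynaptic (MSN) rate.
#' @param theta sliding threshold.
#' @param eta learning rate.
#' @param dt time step.
#' @param w_min,w_max hard weight bounds.
#' @return Updated weight.
#' @export
weight_update <- function(w, x, y, theta, eta, dt, w_min = 0, w_max = 2) {
  cpp_weight_update(w, x, y, theta, eta, dt, w_min, w_max)
}

#' Update the postsynaptic activity tracker
#'
#' Exponential moving average of `y^2` with time constant `ysq_tau`; its
#' fixed point for constant `y` is `y^2`.
#'
#' @param tracker current estimate.
#' @param y postsynaptic rate.
#' @param dt time step.
#' @param ysq_tau averaging time constant in seconds.
#' @return Updated tracker.
#' @export
update_ysq <- function(tracker, y, dt, ysq_tau = 5) {
  if (ysq_tau <= 0) stop("ysq_tau must be positive")
  cpp_update_ysq(tracker, y, dt, ysq_tau)
}
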