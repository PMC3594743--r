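#' Superior-colliculus response to a phasic feature
#'
#' The collicular detector responds to the rectified part of the feature not
#' already predicted: `[y_f - y*]^+`.
#'
#' @param y_f binary flash feature (0 or 1).
#' @param y_star phasic prediction in \[0, 1\].
#' @return Collicular response amplitude.
#' @export
sc_response <- function(y_f, y_star) {
  cpp_sc_response(y_f, y_star)
}

#' Canceling signal
#'
#' The similarly timed inhibitory signal carrying the rectified part of the
#' prediction not matched by the feature: `[y* - y_f]^+`.
#'
#' @inheritParams sc_response
#' @return Canceling-signal amplitude.
#' @export
cancel_signal <- function(y_f, y_star) {
  cpp_cancel_signal(y_f, y_star)
}

#' Sensory prediction error
#'
#' `e = y_sc - y_cancel`, which by construction equals `y_f - y*`.
#'
#' @param y_sc collicular response.
#' @param y_cancel canceling signal.
#' @return The signed prediction error.
#' @export
prediction_error <- function(y_sc, y_cancel) {
  y_sc - y_cancel
}

#' Effective input to a dopamine neuron
#'
#' Burst and dip pathways are weighted asymmetrically:
#' `I = a+ * y_sc - a- * y_cancel` with defaults `a+` = 2, `a-` = 1.
#'
#' @inheritParams prediction_error
#' @param a_plus burst gain.
#' @param a_minus dip gain.
#' @return SNc input.
#' @export
snc_input <- function(y_sc, y_cancel, a_plus = 2, a_minus = 1) {
  cpp_snc_input(y_sc, y_cancel, a_plus, a_minus)
}

#' SNc output: simulated dopamine level
#'
#' Unnormalized read-out of the SNc activation: `d = max(0, a + 0.2)`.
#' Resting activation 0 gives the tonic level d = 0.2; bursts rise above it
#' without saturation; dips are rectified at zero.
#'
#' @param a_snc SNc activation(s) from leaky integration of [snc_input()].
#' @return Dopamine level(s) `d >= 0`.
#' @export
#' @examples
#' snc_output(c(-0.3, 0, 1))  # 0, 0.2, 1.2
snc_output <- function(a_snc) {
  cpp_snc_output(as.numeric(a_snc))
}

#' Triangular event pulse
#'
#' Collicular and canceling responses are phenomenological triangular pulses
#' of width 0.2 s: zero outside the event window, linear rise to the
#' amplitude at the window center, linear fall back to zero.
#'
#' @param t evaluation time(s).
#' @param t_event event onset.
#' @param width pulse width in seconds.
#' @param amplitude peak value.
#' @return Pulse value(s).
#' @export
triangular_pulse <- function(t, t_event, width = 0.2, amplitude = 1) {
  if (width <= 0) stop("width must be positive")
  cpp_triangular_pulse(as.numeric(t), t_event, width, amplitude)
}

#' Simulate the dopamine transient for one event
#'
#' Convenience probe: integrates the SNc unit over an isolated phasic event
#' and returns the dopamine time course, as consumed by the plasticity rule.
#'
#' @param y_f binary flash feature.
#' @param y_star phasic prediction at the event.
#' @param cfg a full configuration ([default_config()]).
#' @param duration seconds to simulate from event onset.
#' @return A data.frame with columns `time` and `d`.
#' @export
dopamine_transient <- function(y_f, y_star, cfg = default_config(),
                               duration = 1) {
  dt <- cfg$network$dt
  da <- cfg$dopamine
  y_sc <- sc_response(y_f, y_star)
  y_can <- cancel_signal(y_f, y_star)
  tt <- seq(0, duration, by = dt)
  a <- 0
  d <- numeric(length(tt))
  d[1] <- snc_output(a)
  for (i in seq_along(tt)[-1]) {
    I <- snc_input(triangular_pulse(tt[i], 0, da$pulse_width, y_sc),
                   triangular_pulse(tt[i], 0, da$pulse_width, y_can),
                   da$a_plus, da$a_minus)
    a <- integrate_unit(a, I, dt, da$tau)
    d[i] <- snc_output(a)
  }
  data.frame(time = tt, d = d)
}
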