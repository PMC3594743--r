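#' Leaky-integrator unit step
#'
#' One forward-Euler step of the unit equation
#' \eqn{\tau \, da/dt = -a + I}: the building block of every population in
#' the selection network.
#'
#' @param a activation (scalar or vector).
#' @param I summed weighted input.
#' @param dt time step in seconds; must satisfy `0 < dt <= tau`.
#' @param tau membrane time constant in seconds (default 0.04).
#' @return Updated activation(s).
#' @export
#' @examples
#' integrate_unit(0, 1, dt = 0.01, tau = 0.04)  # 0.25
integrate_unit <- function(a, I, dt, tau = 0.04) {
  if (tau <= 0) stop("tau must be positive")
  if (dt <= 0 || dt > tau)
    stop("integration-stability error: require 0 < dt <= tau")
  cpp_integrate_unit(as.numeric(a), as.numeric(I), dt, tau)
}

#' Piecewise-linear squashing function
#'
#' Maps an activation to a normalized firing rate: 0 at or below the
#' threshold `eps`, unit slope above it, saturating at 1.
#'
#' @param a activation (scalar or vector).
#' @param eps output threshold; negative values give tonic activity at rest.
#' @return Rate(s) in \[0, 1\].
#' @export
#' @examples
#' squash_rate(c(0.1, 0.7, 2), eps = 0.2)
squash_rate <- function(a, eps) {
  cpp_squash(as.numeric(a), eps)
}

#' Tonic-dopamine scaling of cortico-striatal weights
#'
#' A constant tonic dopamine level `lambda` facilitates transmission at
#' D1-expressing MSNs by the factor `1 + lambda` and attenuates it at
#' D2-expressing MSNs by `1 - lambda`.
#'
#' @param w non-negative weight(s).
#' @param lambda tonic dopamine level in \[0, 1).
#' @param receptor `"D1"` or `"D2"`.
#' @return Effective weight(s).
#' @export
effective_cortico_striatal_weight <- function(w, lambda, receptor = c("D1", "D2")) {
  receptor <- match.arg(receptor)
  if (any(w < 0)) stop("weights must be non-negative")
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  cpp_effective_weight(as.numeric(w), lambda, receptor == "D1")
}

#' Resting network state
#'
#' All activations and outputs zero; after settling with zero salience the
#' tonically active nuclei (STN, GPe, GPi/SNr) recover their positive resting
#' rates.
#'
#' @return A named list of population states, each with activation vector `a`
#'   and output vector `y` (one entry per action channel).
#' @export
network_rest_state <- function() {
  cpp_network_rest()
}

#' Default cortico-striatal weights
#'
#' Motor weights at `motor`, sensory weights at exactly zero (sensory bias is
#' acquired only through learning).
#'
#' @param motor common initial motor weight for all three channels.
#' @return A list with components `m_d1`, `s_d1`, `m_d2`, `s_d2` (length-3
#'   numeric vectors).
#' @export
initial_weights <- function(motor = 0.5) {
  list(m_d1 = rep(motor, 3), s_d1 = rep(0, 3),
       m_d2 = rep(motor, 3), s_d2 = rep(0, 3))
}

#' Advance the selection network
#'
#' Steps the full basal-ganglia / thalamocortical / brainstem network under a
#' static per-channel salience input.
#'
#' @param state a network state as returned by [network_rest_state()] or a
#'   previous call.
#' @param saliences length-3 numeric vector of per-channel salience.
#' @param weights cortico-striatal weights ([initial_weights()] format).
#' @param net_cfg the `network` section of a configuration.
#' @param duration simulated seconds to advance.
#' @param noise_sd per-step input noise (default 0 for deterministic probes).
#' @return The advanced network state.
#' @export
step_network <- function(state, saliences, weights,
                         net_cfg = default_config()$network,
                         duration = 1, noise_sd = 0) {
  n_steps <- max(1L, as.integer(round(duration / net_cfg$dt)))
  cpp_network_run(state, as.numeric(saliences), weights, net_cfg,
                  n_steps, noise_sd)
}

#' Settle the network and report selection
#'
#' Runs the network to (near) equilibrium under static saliences and returns
#' the brainstem outputs, GPi/SNr outputs, and the set of selected channels.
#'
#' @inheritParams step_network
#' @param duration settling time in seconds (1 s reaches equilibrium at the
#'   default gains).
#' @return A list with `y_bs`, `y_gpi`, `selected` (integer channel indices)
#'   and the final `state`.
#' @export
settle_network <- function(saliences, weights,
                           net_cfg = default_config()$network,
                           duration = 1) {
  st <- step_network(network_rest_state(), saliences, weights, net_cfg,
                     duration = duration, noise_sd = 0)
  y_bs <- st$bs$y
  list(y_bs = y_bs,
       y_gpi = st$gpi$y,
       selected = select_actions(y_bs, net_cfg$phi),
       state = st)
}

#' Threshold selection of action channels
#'
#' A channel is selected for behavioral expression when its brainstem output
#' exceeds the threshold `phi`. The result may be empty (no action) or
#' contain several channels (motor blending then averages their commands).
#'
#' @param y_bs brainstem output vector.
#' @param phi selection threshold (default 0.5).
#' @return Integer vector of selected channel indices.
#' @export
select_actions <- function(y_bs, phi = 0.5) {
  which(y_bs > phi)
}

#' Selection-competence battery
#'
#' Probes the settled network on a grid of static salience pairs
#' `(s1, s2)` on channels 1 and 2 with channel 3 silent. A cell passes when
#' either nothing is selected, or the channel with the larger salience is
#' among the selected and every selected channel lies within 0.2 of the
#' maximum salience — saliences separated by at least 0.2 must never
#' produce simultaneous selection, while transient co-selection of
#' near-ties is tolerated (motor blending then averages their commands).
#'
#' @param weights cortico-striatal weights.
#' @param net_cfg the `network` section of a configuration.
#' @param grid numeric vector of salience values for each axis.
#' @return A list with `pass` (logical), `n_checked`, `n_failed`,
#'   `n_unselected_mid` (cells with max salience >= 0.3 selecting nothing —
#'   a sensitivity diagnostic, not a failure), and a data.frame `results`.
#' @export
selection_battery <- function(weights, net_cfg = default_config()$network,
                              grid = seq(0, 1, by = 0.1)) {
  res <- expand.grid(s1 = grid, s2 = grid)
  res$selected1 <- FALSE
  res$selected2 <- FALSE
  res$none <- FALSE
  res$ok <- TRUE
  for (i in seq_len(nrow(res))) {
    s <- c(res$s1[i], res$s2[i], 0)
    sel <- settle_network(s, weights, net_cfg)$selected
    res$selected1[i] <- 1L %in% sel
    res$selected2[i] <- 2L %in% sel
    res$none[i] <- length(sel) == 0
    if (length(sel)) {
      mx <- max(s)
      if (!(which.max(s) %in% sel) || any(mx - s[sel] >= 0.2 - 1e-9))
        res$ok[i] <- FALSE
    }
  }
  list(pass = all(res$ok), n_checked = nrow(res),
       n_failed = sum(!res$ok),
       n_unselected_mid = sum(res$none & pmax(res$s1, res$s2) >= 0.3),
       results = res)
}

#' Calibrate motor weights
#'
#' An initial weight-calibration pass: finds the common motor
#' cortico-striatal weight under which each of the three actions is cleanly
#' selected when its salience dominates, verified by the selection battery.
#' Candidate weights on a ladder are screened on a coarse salience grid and
#' the best few are verified on the full battery; the score penalizes any
#' wrong-winner cell outright and otherwise prefers the weight that keeps
#' moderate saliences selectable. The procedure is deterministic.
#'
#' @param net_cfg the `network` section of a configuration.
#' @param probe salience given to the probed channel (competitors at 0.2)
#'   in the per-channel selectability check.
#' @param ladder candidate common motor weights.
#' @return Calibrated weights ([initial_weights()] format), with attribute
#'   `"battery"` holding the verification summary.
#' @export
calibrate_motor_weights <- function(net_cfg = default_config()$network,
                                    probe = 0.6,
                                    ladder = seq(0.6, 1.5, by = 0.05)) {
  each_selectable <- function(w) {
    all(vapply(1:3, function(ch) {
      s <- rep(0.2, 3)
      s[ch] <- probe
      identical(settle_network(s, w, net_cfg)$selected, ch)
    }, logical(1)))
  }
  score <- function(w, grid) {
    bat <- selection_battery(w, net_cfg, grid)
    none_mid <- bat$results$none & pmax(bat$results$s1, bat$results$s2) >= 0.3
    none_hi <- bat$results$none & pmax(bat$results$s1, bat$results$s2) >= 0.5
    1000 * bat$n_failed + sum(none_mid) + 2 * sum(none_hi)
  }
  coarse <- seq(0, 1, by = 0.2)
  ok <- Filter(function(w0) each_selectable(initial_weights(w0)), ladder)
  if (!length(ok))
    stop("calibration failure: no candidate weight makes every action ",
         "selectable when its salience dominates")
  sc <- vapply(ok, function(w0) score(initial_weights(w0), coarse),
               numeric(1))
  short <- ok[order(sc)][seq_len(min(3, length(ok)))]
  full <- vapply(short, function(w0)
    score(initial_weights(w0), seq(0, 1, by = 0.1)), numeric(1))
  w0 <- short[which.min(full)]
  w <- initial_weights(w0)
  bat <- selection_battery(w, net_cfg)
  if (!bat$pass)
    stop("calibration failure: selection battery failed at weight ", w0,
         " (", bat$n_failed, " of ", bat$n_checked, " cells)")
  attr(w, "battery") <- bat[c("pass", "n_checked", "n_failed",
                              "n_unselected_mid")]
  w
}
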