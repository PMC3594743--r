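#' Update the latent outcome prediction
#'
#' Recursive phenomenological prediction of the phasic outcome (light flash)
#' attached to a block. A delivered flash moves the prediction toward 1,
#' `y' = 1 - k (1 - y)`; the first-ever flash sets it to 0.2; an omission
#' with a non-zero prediction decays it, `y' = k y`; an omission with a zero
#' prediction leaves it untouched. The latent prediction is constant between
#' interaction events and persists across day boundaries.
#'
#' @param y_latent current latent prediction in \[0, 1\].
#' @param outcome `"flash"` or `"omission"`.
#' @param seen_first has this block ever flashed before?
#' @param k update constant in (0, 1), default 0.95.
#' @return Updated latent prediction.
#' @export
#' @examples
#' update_prediction(0, "flash", seen_first = FALSE)   # first flash: 0.2
#' update_prediction(0.2, "flash", seen_first = TRUE)  # 0.24
update_prediction <- function(y_latent, outcome = c("flash", "omission"),
                              seen_first = TRUE, k = 0.95) {
  outcome <- match.arg(outcome)
  if (k <= 0 || k >= 1) stop("k must be in (0, 1)")
  if (y_latent < 0 || y_latent > 1) stop("y_latent must be in [0, 1]")
  cpp_update_prediction(y_latent, outcome == "flash", seen_first, k)
}

#' Phasic read-out of the prediction
#'
#' At an interaction event the internal model emits the phasic prediction,
#' equal to the current latent value; between events no phasic prediction
#' exists.
#'
#' @param y_latent latent prediction.
#' @return The phasic prediction `y*`.
#' @export
phasic_prediction <- function(y_latent) {
  y_latent
}

#' Novelty salience of a predicted outcome
#'
#' Tent map on the phasic prediction: zero at the firm predictions 0 and 1,
#' maximal (0.5) at the least predictable outcome `y* = 0.5`.
#'
#' @param y_star phasic prediction(s) in \[0, 1\].
#' @return Novelty salience value(s) in \[0, 0.5\].
#' @export
#' @examples
#' novelty_salience(c(0, 0.2, 0.5, 1))  # 0, 0.3, 0.5, 0
novelty_salience <- function(y_star) {
  if (any(y_star < 0 | y_star > 1)) stop("y_star must be in [0, 1]")
  cpp_novelty_salience(as.numeric(y_star))
}

#' Within-day habituation of intrinsic salience
#'
#' After each completed interaction with a block, its intrinsic salience is
#' scaled by the within-day habituation factor.
#'
#' @param s_int current intrinsic salience.
#' @param gamma_b within-day habituation factor in (0, 1\].
#' @return Habituated salience.
#' @export
habituate_within_day <- function(s_int, gamma_b = 0.95) {
  if (gamma_b <= 0 || gamma_b > 1) stop("gamma_b must be in (0, 1]")
  s_int * gamma_b
}

#' Across-day dishabituation of intrinsic salience
#'
#' The day-start salience is the previous day's \emph{first-interaction}
#' value scaled by `gamma_a` — not the previous day's last (habituated)
#' value, which is what produces partial overnight recovery
#' (dishabituation).
#'
#' @param s_day_start_prev the previous day's day-start intrinsic salience.
#' @param gamma_a across-day habituation factor in (0, 1\].
#' @return The new day-start intrinsic salience.
#' @export
dishabituate_across_days <- function(s_day_start_prev, gamma_a = 0.95) {
  if (gamma_a <= 0 || gamma_a > 1) stop("gamma_a must be in (0, 1]")
  s_day_start_prev * gamma_a
}

#' Total salience of a block
#'
#' Sum of intrinsic (habituating) salience and novelty salience, applied
#' while the block is in view.
#'
#' @param s_int intrinsic salience.
#' @param s_nov novelty salience.
#' @return Total salience.
#' @export
total_salience <- function(s_int, s_nov) {
  s_int + s_nov
}

#' Draw explore salience
#'
#' The motivation to explore is drawn from Uniform(0, 0.8): mean 0.4 and
#' standard deviation 0.8/sqrt(12) = 0.231. Redrawn once per simulated
#' second inside the engine.
#'
#' @param n number of draws.
#' @param max upper bound of the uniform support.
#' @return Numeric vector of draws.
#' @export
explore_salience <- function(n = 1, max = 0.8) {
  stats::runif(n, 0, max)
}
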