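#' Initial persistent state for a run
#'
#' Bundles everything carried across virtual days: cortico-striatal weights,
#' the per-block latent predictions (zero until the first flash), per-block
#' day-start intrinsic saliences, and the MSN activity trackers.
#'
#' @param weights cortico-striatal weights ([initial_weights()] or
#'   [calibrate_motor_weights()]).
#' @param cfg a full configuration.
#' @return A persistent-state list.
#' @export
initial_persist <- function(weights, cfg = default_config()) {
  list(weights = weights,
       y_latent = c(0, 0),
       seen_first = c(FALSE, FALSE),
       s_int = rep(cfg$prediction$s_init, 2),
       s_day_start = rep(cfg$prediction$s_init, 2),
       ysq_d1 = rep(0, 3),
       ysq_d2 = rep(0, 3))
}

#' Run one virtual day (session)
#'
#' Simulates the full closed loop — salience generation, selection network,
#' action subsystems, arena kinematics, schedule gating, phasic dopamine and
#' plasticity — for one session. Day-boundary dishabituation is applied
#' here: for `day_index > 1` the day-start intrinsic salience of each block
#' is `gamma_a` times the previous day's day-start value.
#'
#' @param persist persistent state from [initial_persist()] or a previous
#'   day's result.
#' @param day_index 1-based day number.
#' @param cfg full configuration.
#' @param schedule `"VI"` or `"FR1"`.
#' @param pda logical; phasic dopamine pathway enabled?
#' @param contingent logical; is this a response-contingent day? (FALSE
#'   during habituation: no flashes regardless of schedule.)
#' @param record_dense logical; record per-step traces (dopamine level, red
#'   salience, red brainstem output, selection mask).
#' @return A list with `interactions` (data.frame), `weight_snapshots`
#'   (matrix, one row per interaction, 12 columns: motor/sensory x D1/D2 x 3
#'   channels), `flash_times`, `persist` (state to carry to the next day)
#'   and optionally `dense`.
#' @export
run_session <- function(persist, day_index, cfg = default_config(),
                        schedule = c("VI", "FR1"), pda = TRUE,
                        contingent = FALSE, record_dense = FALSE) {
  schedule <- match.arg(schedule)
  # day-start salience: gamma_a times the previous day's *day-start* value
  # (not its within-day habituated end value), which yields overnight
  # dishabituation
  if (day_index > 1)
    persist$s_day_start <- dishabituate_across_days(persist$s_day_start,
                                                    cfg$prediction$gamma_a)
  persist$s_int <- persist$s_day_start
  out <- cpp_run_session(persist, cfg, if (schedule == "FR1") 1L else 0L,
                         pda, contingent, record_dense)
  out$persist$s_day_start <- persist$s_day_start
  out$interactions <- as.data.frame(out$interactions)
  out$dopamine_events <- as.data.frame(out$dopamine_events)
  colnames(out$weight_snapshots) <- weight_snapshot_columns()
  if (!is.null(out$dense)) out$dense <- as.data.frame(out$dense)
  out
}

weight_snapshot_columns <- function() {
  ch <- c("explore", "red", "white")
  as.vector(vapply(c("m_d1", "s_d1", "m_d2", "s_d2"),
                   function(g) paste(g, ch, sep = "."), character(3)))
}
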