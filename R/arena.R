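#' Step the differential-drive kinematics
#'
#' Standard two-wheel kinematics: forward speed is the wheel-speed mean,
#' turn rate their difference over the wheel base. The agent is clamped
#' inside the arena walls and pushed out of the (static) blocks — the arena
#' is kinematic, with no mass or friction.
#'
#' @param pose numeric `c(x, y, heading)`.
#' @param z numeric `c(z_l, z_r)` wheel speeds.
#' @param dt time step in seconds.
#' @param arena_cfg the `arena` section of a configuration.
#' @return The new pose `c(x, y, heading)`.
#' @export
step_kinematics <- function(pose, z, dt, arena_cfg = default_config()$arena) {
  cpp_step_kinematics(as.numeric(pose), as.numeric(z), dt, arena_cfg)
}

#' Perceive the arena
#'
#' A block is visible when it lies within the forward field-of-view cone and
#' viewing range; contact is registered when the agent body is within the
#' contact margin of the block.
#'
#' @param pose numeric `c(x, y, heading)`.
#' @param arena_cfg the `arena` section of a configuration.
#' @return A list with `red_visible`, `white_visible`, `red_contact`,
#'   `white_contact`, `red_dist`, `white_dist`.
#' @export
perceive <- function(pose, arena_cfg = default_config()$arena) {
  cpp_perceive(as.numeric(pose), arena_cfg)
}

#' Blend motor commands of selected subsystems
#'
#' Component-wise mean of the wheel-speed vectors of all selected action
#' subsystems; the zero vector when none is selected.
#'
#' @param commands a list of numeric `c(z_l, z_r)` vectors (possibly empty).
#' @return A single blended `c(z_l, z_r)`.
#' @export
#' @examples
#' blend_motors(list(c(4, 4), c(-4, -4)))  # cancels to c(0, 0)
blend_motors <- function(commands) {
  if (length(commands) == 0) return(c(0, 0))
  Reduce(`+`, commands) / length(commands)
}

#' Create a reinforcement-schedule state
#'
#' @param kind `"VI"` (variable interval) or `"FR1"` (fixed ratio 1).
#' @param vi_mean mean of the exponential inter-availability interval (s).
#' @param t current time (used to draw the first VI interval).
#' @return A schedule-state list with `kind`, `vi_mean`, `next_avail`.
#' @export
schedule_state <- function(kind = c("VI", "FR1"), vi_mean = 120, t = 0) {
  kind <- match.arg(kind)
  if (vi_mean <= 0) stop("vi_mean must be positive")
  list(kind = kind, vi_mean = vi_mean,
       next_avail = if (kind == "VI") t + stats::rexp(1, 1 / vi_mean) else 0)
}

#' Gate a red-block bump through the reinforcement schedule
#'
#' Under FR1 every bump on the active (red) block flashes. Under VI a bump
#' flashes only if the drawn interval has elapsed (the schedule is armed);
#' a premature bump yields no flash and leaves the schedule armed-to-be.
#' On a flash the VI schedule re-arms after a fresh Exponential(mean
#' `vi_mean`) interval. Bumps on the white block never flash and should not
#' be passed to this gate.
#'
#' @param schedule a schedule state from [schedule_state()].
#' @param t time of the bump.
#' @return A list with `flash` (logical) and the updated `schedule`.
#' @export
schedule_gate <- function(schedule, t) {
  if (schedule$kind == "FR1") return(list(flash = TRUE, schedule = schedule))
  if (t >= schedule$next_avail) {
    schedule$next_avail <- t + stats::rexp(1, 1 / schedule$vi_mean)
    list(flash = TRUE, schedule = schedule)
  } else {
    list(flash = FALSE, schedule = schedule)
  }
}
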