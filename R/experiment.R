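#' Run a complete multi-day experiment
#'
#' Runs `n_runs` independent replicates of the full protocol: a habituation
#' phase (no flashes) followed by a response-contingent phase under the
#' given schedule, carrying weights, predictions and day-start saliences
#' across days within each replicate. Replicate `r` is seeded with
#' `base_seed + r - 1`, covering every stochastic element (network noise,
#' explore salience, initial heading, VI intervals).
#'
#' @param cfg full configuration ([default_config()]).
#' @param schedule `"VI"` or `"FR1"`.
#' @param pda logical; phasic dopamine enabled.
#' @param n_runs number of replicates (default from `cfg$protocol`).
#' @param base_seed base RNG seed (default from `cfg$protocol`).
#' @param weights optional pre-calibrated weights; calibrated once from the
#'   configuration when omitted.
#' @param progress print per-session progress.
#' @return An object of class `ad_experiment`: a list with `responses`
#'   (data.frame: run, day, phase, epoch, block, count), `weights`
#'   (data.frame: time, run, receptor, source, channel, weight),
#'   `events` (per-interaction records with run and day), `config`,
#'   `schedule`, `pda`, `n_runs`, `failed_runs`.
#' @export
run_experiment <- function(cfg = default_config(), schedule = c("VI", "FR1"),
                           pda = TRUE, n_runs = cfg$protocol$n_runs,
                           base_seed = cfg$protocol$base_seed,
                           weights = NULL, progress = FALSE) {
  schedule <- match.arg(schedule)
  cfg <- validate_config(cfg)
  if (is.null(weights)) weights <- calibrate_motor_weights(cfg$network)
  n_hab <- cfg$protocol$days_habituation
  n_rc <- cfg$protocol$days_rc
  n_days <- n_hab + n_rc
  epoch_len <- cfg$protocol$epoch_length
  sess_len <- cfg$protocol$session_length
  n_epochs <- max(1L, as.integer(round(sess_len / epoch_len)))

  resp <- list()
  wts <- list()
  evs <- list()
  failed <- integer(0)

  for (r in seq_len(n_runs)) {
    run_res <- tryCatch({
      set.seed(base_seed + r - 1L)
      persist <- initial_persist(weights, cfg)
      day_rows <- list()
      wt_rows <- list()
      ev_rows <- list()
      for (day in seq_len(n_days)) {
        contingent <- day > n_hab
        out <- run_session(persist, day, cfg, schedule, pda, contingent)
        persist <- out$persist
        it <- out$interactions
        t0 <- (day - 1) * sess_len
        for (ep in seq_len(n_epochs)) {
          lo <- (ep - 1) * epoch_len
          hi <- ep * epoch_len
          in_ep <- it$time >= lo & it$time < hi
          for (b in 1:2) {
            day_rows[[length(day_rows) + 1]] <- data.frame(
              run = r, day = day,
              phase = if (contingent) "RC" else "H",
              epoch = ep, block = c("red", "white")[b],
              count = sum(in_ep & it$block == b))
          }
        }
        if (nrow(it)) {
          snap <- out$weight_snapshots
          wt_rows[[length(wt_rows) + 1]] <- data.frame(
            time = t0 + it$time,
            run = r,
            snap, check.names = FALSE)
          it$run <- r
          it$day <- day
          it$time_global <- t0 + it$time
          ev_rows[[length(ev_rows) + 1]] <- it
        }
        if (progress)
          message(sprintf("run %d day %d: %d red, %d white, %d flashes",
                          r, day, sum(it$block == 1), sum(it$block == 2),
                          length(out$flash_times)))
      }
      list(resp = do.call(rbind, day_rows),
           wts = do.call(rbind, wt_rows),
           evs = do.call(rbind, ev_rows))
    }, error = function(e) e)
    if (inherits(run_res, "error")) {
      warning("run ", r, " failed: ", conditionMessage(run_res))
      failed <- c(failed, r)
    } else {
      resp[[length(resp) + 1]] <- run_res$resp
      wts[[length(wts) + 1]] <- run_res$wts
      evs[[length(evs) + 1]] <- run_res$evs
    }
  }

  if (length(failed) > 0.2 * n_runs)
    stop("too many failed runs (", length(failed), " of ", n_runs, ")")

  wide <- do.call(rbind, wts)
  structure(list(
    responses = do.call(rbind, resp),
    weights = weights_long(wide),
    events = do.call(rbind, evs),
    config = cfg, schedule = schedule, pda = pda,
    n_runs = n_runs, failed_runs = failed,
    days_habituation = n_hab, days_rc = n_rc
  ), class = "ad_experiment")
}

# wide snapshot columns -> long (time, run, receptor, source, channel, weight)
weights_long <- function(wide) {
  if (is.null(wide) || !nrow(wide)) return(NULL)
  cols <- weight_snapshot_columns()
  out <- lapply(cols, function(cn) {
    parts <- strsplit(cn, "[._]")[[1]]  # e.g. "m", "d1", "red"
    data.frame(time = wide$time, run = wide$run,
               receptor = toupper(parts[2]),
               source = if (parts[1] == "m") "motor" else "sensory",
               channel = parts[3],
               weight = wide[[cn]])
  })
  do.call(rbind, out)
}

#' @export
print.ad_experiment <- function(x, ...) {
  cat("Embodied action-discovery experiment\n")
  cat(sprintf("  schedule: %s, phasic dopamine: %s, runs: %d (%d failed)\n",
              x$schedule, if (x$pda) "on" else "off", x$n_runs,
              length(x$failed_runs)))
  dc <- daily_counts(x)
  rc <- dc[dc$phase == "RC", ]
  cat(sprintf("  days: %d habituation + %d response-contingent\n",
              x$days_habituation, x$days_rc))
  cat(sprintf("  RC phase: peak active/day %.1f (day %d), mean inactive/day %.2f\n",
              max(rc$active), rc$day[which.max(rc$active)],
              mean(rc$inactive)))
  cat(sprintf("  r_peak = %d\n", r_peak_from_experiment(x)))
  invisible(x)
}

#' Per-day response counts averaged over runs
#'
#' @param exp an `ad_experiment`.
#' @return A data.frame with `day`, `phase`, `active`, `inactive` (mean
#'   counts across runs).
#' @export
daily_counts <- function(exp) {
  resp <- exp$responses
  agg <- stats::aggregate(count ~ run + day + phase + block, resp, sum)
  red <- stats::aggregate(count ~ day + phase,
                          agg[agg$block == "red", ], mean)
  white <- stats::aggregate(count ~ day + phase,
                            agg[agg$block == "white", ], mean)
  out <- merge(red, white, by = c("day", "phase"),
               suffixes = c(".red", ".white"))
  out <- out[order(out$day), ]
  data.frame(day = out$day, phase = out$phase,
             active = out$count.red, inactive = out$count.white)
}

#' Peak-to-inactive response ratio
#'
#' The ratio, rounded to the nearest integer (half-up), of the peak daily
#' active-response count during the response-contingent phase to the mean
#' daily inactive-response count over that phase.
#'
#' @param active_per_day daily active counts over the RC phase (typically
#'   means across runs).
#' @param inactive_per_day daily inactive counts over the RC phase.
#' @return Integer ratio, or `NA` if the mean inactive count is zero.
#' @export
#' @examples
#' r_peak(c(10, 20, 15), c(5, 5, 5))  # 4
r_peak <- function(active_per_day, inactive_per_day) {
  m <- mean(inactive_per_day)
  if (m == 0) return(NA_integer_)
  as.integer(floor(max(active_per_day) / m + 0.5))
}

#' @describeIn r_peak compute r_peak directly from an experiment.
#' @param exp an `ad_experiment`.
#' @export
r_peak_from_experiment <- function(exp) {
  dc <- daily_counts(exp)
  rc <- dc[dc$phase == "RC", ]
  r_peak(rc$active, rc$inactive)
}

#' Within-day epoch profile
#'
#' Interaction counts binned into session epochs, averaged over the
#' response-contingent days and runs.
#'
#' @param exp an `ad_experiment`.
#' @param block `"red"` or `"white"`.
#' @return Numeric vector of mean counts, one per epoch.
#' @export
epoch_counts <- function(exp, block = "red") {
  resp <- exp$responses
  sel <- resp[resp$phase == "RC" & resp$block == block, ]
  agg <- stats::aggregate(count ~ epoch, sel, mean)
  stats::setNames(agg$count, paste0("epoch", agg$epoch))
}

#' Habituation-phase symmetry test
#'
#' Two-sided paired sign-flip permutation test of the per-run difference
#' between total active and inactive responses during the habituation phase.
#' Before any contingency the red/white labels are arbitrary, so the
#' difference should be exchangeable around zero.
#'
#' @param exp an `ad_experiment`.
#' @param n_perm number of sign-flip resamples (exact enumeration when the
#'   number of runs allows).
#' @return A list with `p_value`, `mean_diff`, and per-run totals.
#' @export
habituation_symmetry_test <- function(exp, n_perm = 10000) {
  resp <- exp$responses
  hab <- resp[resp$phase == "H", ]
  agg <- stats::aggregate(count ~ run + block, hab, sum)
  red <- agg$count[agg$block == "red"][order(agg$run[agg$block == "red"])]
  white <- agg$count[agg$block == "white"][order(agg$run[agg$block == "white"])]
  d <- red - white
  n <- length(d)
  obs <- abs(mean(d))
  if (n <= 20) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% d) / n
    p <- mean(stat >= obs - 1e-12)
  } else {
    stat <- replicate(n_perm, abs(mean(d * sample(c(-1, 1), n, TRUE))))
    p <- (sum(stat >= obs - 1e-12) + 1) / (n_perm + 1)
  }
  list(p_value = p, mean_diff = mean(d), active = red, inactive = white)
}

#' Mean weight trajectory across runs
#'
#' Each run's piecewise-constant weight series (snapshots at interaction
#' times) is interpolated onto a common time grid and averaged across runs.
#'
#' @param exp an `ad_experiment`.
#' @param receptor `"D1"` or `"D2"`.
#' @param source `"motor"` or `"sensory"`.
#' @param channel `"red"`, `"white"` or `"explore"`.
#' @param grid_step grid spacing in seconds.
#' @return A data.frame with `time` and `weight` (mean across runs).
#' @export
mean_weight_trajectory <- function(exp, receptor = "D1", source = "motor",
                                   channel = "red", grid_step = 30) {
  w <- exp$weights
  w <- w[w$receptor == receptor & w$source == source &
           w$channel == channel, ]
  total_t <- (exp$days_habituation + exp$days_rc) *
    exp$config$protocol$session_length
  grid <- seq(0, total_t, by = grid_step)
  runs <- unique(w$run)
  tr <- vapply(runs, function(r) {
    wr <- w[w$run == r, ]
    wr <- wr[order(wr$time), ]
    if (!nrow(wr)) return(rep(NA_real_, length(grid)))
    # step function, carried forward; initial value before first snapshot
    stats::approx(c(0, wr$time), c(wr$weight[1], wr$weight),
                  xout = grid, method = "constant", rule = 2)$y
  }, numeric(length(grid)))
  data.frame(time = grid, weight = rowMeans(tr, na.rm = TRUE))
}

#' Weight-change summary over the response-contingent phase
#'
#' For each (receptor, source) pair of the active-response channel, reports
#' the mean weight at the onset of the response-contingent phase, the
#' maximum over the phase, the final value, and the relative change.
#'
#' @param exp an `ad_experiment`.
#' @return A data.frame with one row per receptor/source combination.
#' @export
weight_change_summary <- function(exp) {
  rc_start <- exp$days_habituation * exp$config$protocol$session_length
  out <- list()
  for (rec in c("D1", "D2")) for (src in c("motor", "sensory")) {
    tr <- mean_weight_trajectory(exp, rec, src, "red")
    rc <- tr[tr$time >= rc_start, ]
    onset <- rc$weight[1]
    peak_i <- which.max(rc$weight)
    out[[length(out) + 1]] <- data.frame(
      receptor = rec, source = src,
      onset = onset, peak = rc$weight[peak_i],
      peak_time = rc$time[peak_i],
      final = rc$weight[nrow(rc)],
      rel_change = if (onset > 0) (rc$weight[nrow(rc)] - onset) / onset
                   else NA_real_)
  }
  do.call(rbind, out)
}
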