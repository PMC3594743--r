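#' Write experiment outputs
#'
#' Writes `responses.csv`, `weights.csv`, `events.csv` and `summary.json`
#' for an experiment into a directory. Every CSV starts with a comment
#' header carrying the configuration hash and base seed, so outputs are
#' traceable and bitwise reproducible for a given configuration and seed.
#'
#' @param exp an `ad_experiment`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# actiondiscovery config=%s seed=%d schedule=%s pda=%s",
                 config_hash(exp$config), exp$config$protocol$base_seed,
                 exp$schedule, if (exp$pda) "on" else "off")
  wr <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(exp$responses, "responses.csv")
  wr(exp$weights, "weights.csv")
  wr(exp$events, "events.csv")
  dc <- daily_counts(exp)
  rc <- dc[dc$phase == "RC", ]
  summary <- list(
    config_hash = config_hash(exp$config),
    base_seed = exp$config$protocol$base_seed,
    schedule = exp$schedule, pda = exp$pda,
    n_runs = exp$n_runs, failed_runs = exp$failed_runs,
    r_peak = r_peak_from_experiment(exp),
    peak_day = rc$day[which.max(rc$active)],
    first_rc_day = exp$days_habituation + 1,
    mean_inactive_rc = mean(rc$inactive),
    peak_active_rc = max(rc$active),
    epoch_counts_active = as.list(epoch_counts(exp, "red")),
    epoch_counts_inactive = as.list(epoch_counts(exp, "white")))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
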