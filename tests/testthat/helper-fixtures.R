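# Shared fixtures: the calibrated weights are deterministic given the
# network configuration, so compute them once per test run.
ad_cfg <- default_config()
ad_weights <- calibrate_motor_weights(ad_cfg$network)

# A shortened protocol for engine-level tests (2 + 3 days, 2 runs).
ad_short_cfg <- local({
  cfg <- default_config()
  cfg$protocol$days_habituation <- 2
  cfg$protocol$days_rc <- 3
  cfg$protocol$n_runs <- 2
  cfg
})

run_days <- function(n_days, schedule = "VI", pda = TRUE, seed = 1,
                     cfg = ad_cfg, hab_days = cfg$protocol$days_habituation,
                     keep = "last") {
  set.seed(seed)
  p <- initial_persist(ad_weights, cfg)
  outs <- list()
  for (day in seq_len(n_days)) {
    out <- run_session(p, day, cfg, schedule, pda,
                       contingent = day > hab_days)
    p <- out$persist
    if (keep == "all") outs[[day]] <- out
  }
  if (keep == "all") outs else out
}
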