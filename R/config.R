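#' Default model configuration
#'
#' Returns the full nested configuration for the model: network constants and
#' gains, prediction/salience constants, dopamine parameters, plasticity rule
#' constants, arena geometry and speeds, schedule and protocol settings.
#' Values not free to vary (membrane time constant \eqn{\tau} = 0.04 s,
#' selection threshold \eqn{\phi} = 0.5, prediction constant k = 0.95,
#' initial intrinsic salience 0.45, habituation factors \eqn{\gamma_a =
#' \gamma_b} = 0.95, dopamine gains \eqn{a^+} = 2 and \eqn{a^-} = 1, pulse
#' width 0.2 s, VI mean interval 120 s) carry their standard defaults; the
#' remaining gains belong to the canonical rate-coded basal-ganglia parameter
#' family, with thalamocortical and brainstem gains tuned by the selection
#' battery.
#'
#' @return A nested named list with components `network`, `prediction`,
#'   `dopamine`, `plasticity`, `arena`, `schedule`, `protocol`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$network$phi
default_config <- function() {
  list(
    network = list(
      dt = 0.01,
      tau = 0.04,
      # output thresholds: small positive for striatum (quiet at rest),
      # small negative for the tonically active STN/GPe/GPi-SNr and for
      # the brainstem populations (tonic excitability gated by GPi/SNr)
      eps_ssc = 0, eps_mc = 0, eps_str = 0.1,
      eps_stn = -0.25, eps_gpe = -0.2, eps_gpi = -0.2,
      eps_vl = 0, eps_trn = 0, eps_bs = -0.5,
      # projection gains (canonical family, selection battery tuned)
      w_sm = 0.85, w_vm = 0.5, w_mm = 0.05,
      w_cstn = 1.05, w_gstn = 1.25,
      w_stn_gpi = 0.85, w_stn_gpe = 0.75,
      w_d1_gpi = 1, w_d2_gpe = 1, w_gpe_gpi = 0.23,
      w_cv = 1, w_gv = 1.1, w_tv = 0.12, w_td = 1.4,
      w_ct = 0.16, w_vt = 0.46, w_gt = 0.4,
      w_mb = 0.73, w_gb = 2.5,
      lambda = 0.2,
      phi = 0.5,
      noise_sd = 0.015
    ),
    prediction = list(
      k = 0.95,
      s_init = 0.45,
      gamma_a = 0.95,
      gamma_b = 0.95,
      explore_max = 0.8,   # Uniform(0, 0.8): mean 0.4, sd 0.8/sqrt(12)
      explore_redraw = 2.5
    ),
    dopamine = list(
      a_plus = 2,
      a_minus = 1,
      pulse_width = 0.2,
      tau = 0.04
    ),
    plasticity = list(
      # pair-timing coefficients: unit-scale magnitudes respecting the
      # qualitative pattern (D1 hi: strong LTP / weak LTD; D1 lo: LTD both;
      # D2 lo: uniform LTP; D2 hi: LTD both), normalized so the blended
      # C_BCM at resting dopamine sits near the BCM fixed point
      A_d1_hi_plus = 2.0, A_d1_hi_minus = -0.25,
      A_d1_lo_plus = -1.0, A_d1_lo_minus = -1.21,
      A_d2_lo_plus = 0.5, A_d2_lo_minus = 0.5,
      A_d2_hi_plus = -1.0, A_d2_hi_minus = -0.98,
      tau_ratio = 1,
      k_c = 4,
      eta = 0.012,
      w_min = 0,
      w_max = 2,
      ysq_tau = 5,
      window = 1.0
    ),
    arena = list(
      size = 60,
      block_width = 10,
      block_depth = 6,
      agent_radius = 2.8,
      wheel_base = 5,
      contact_margin = 0.8,
      fov_half_deg = 60,
      view_range = 45,
      v_approach = 8,
      v_slow = 2.5,
      v_back = 3,
      v_explore = 7,
      v_turn = 3,
      v_max = 10,
      t_back = 2.0,
      t_stop = 0.6,
      flash_duration = 0.2,
      lookahead = 6,
      stall_timeout = 15
    ),
    schedule = list(
      vi_mean = 120
    ),
    protocol = list(
      days_habituation = 5,
      days_rc = 10,
      session_length = 900,
      epoch_length = 300,
      n_runs = 10,
      base_seed = 1
    )
  )
}

#' Validate a configuration list
#'
#' Checks structure, rejects unknown keys, and enforces the constraints the
#' model requires (0 < k < 1, 0 <= lambda < 1, dt <= tau, positive time
#' constants and geometry, plasticity coefficient sign pattern).
#'
#' @param cfg a nested configuration list as returned by [default_config()].
#' @return `cfg`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_config <- function(cfg) {
  ref <- default_config()
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(bad))
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    nonnum <- !vapply(cfg[[sec]], function(x)
      is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
    if (any(nonnum))
      stop("non-scalar or non-finite value(s) in '", sec, "': ",
           paste(names(cfg[[sec]])[nonnum], collapse = ", "))
  }
  cfg <- utils::modifyList(ref, cfg)
  with(cfg$prediction, {
    if (k <= 0 || k >= 1) stop("prediction constant k must be in (0, 1)")
    if (s_init <= 0) stop("s_init must be positive")
    if (gamma_a <= 0 || gamma_a > 1 || gamma_b <= 0 || gamma_b > 1)
      stop("habituation factors must be in (0, 1]")
    if (explore_max <= 0) stop("explore_max must be positive")
  })
  with(cfg$network, {
    if (tau <= 0) stop("tau must be positive")
    if (dt <= 0 || dt > tau)
      stop("integration-stability error: require 0 < dt <= tau")
    if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  })
  with(cfg$plasticity, {
    if (eta <= 0) stop("eta must be positive")
    if (w_min < 0 || w_max <= w_min) stop("require 0 <= w_min < w_max")
    if (k_c <= 0 || ysq_tau <= 0 || window <= 0)
      stop("k_c, ysq_tau and window must be positive")
    if (!(A_d1_hi_plus > 0 && A_d1_hi_minus < 0))
      stop("D1(hi) must combine LTP for positive timing with weak LTD")
    if (!(A_d2_lo_plus > 0 && A_d2_lo_minus > 0))
      stop("D2(lo) must give uniform LTP for both timings")
  })
  with(cfg$dopamine, {
    if (pulse_width <= 0 || tau <= 0)
      stop("dopamine pulse width and tau must be positive")
  })
  with(cfg$schedule, if (vi_mean <= 0) stop("vi_mean must be positive"))
  with(cfg$protocol, {
    if (session_length <= 0 || epoch_length <= 0)
      stop("session and epoch lengths must be positive")
    if (days_habituation < 0 || days_rc < 1) stop("invalid day counts")
  })
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) configuration file, fills unspecified keys with
#' their defaults, and validates the result. An empty file yields the full
#' default configuration.
#'
#' @param path path to a YAML or JSON file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Save a configuration file
#'
#' @param cfg a configuration list.
#' @param path destination path; format chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Hash of a configuration
#'
#' Short deterministic fingerprint written into output-file metadata so that
#' results can be traced back to the exact configuration that produced them.
#'
#' @param cfg a configuration list.
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # simple polynomial rolling hash; avoids an external digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
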