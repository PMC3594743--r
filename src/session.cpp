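#include "core.h"
using namespace Rcpp;

// Closed-loop session engine: arena + embedding architecture + biomimetic
// core, advanced together at the network time step. One call simulates one
// virtual day (a 15-min session by default). All stochastic draws come from
// the R RNG so a set.seed() on the R side makes a session bitwise
// reproducible.

namespace {

using namespace ad;

// ---------------------------- arena geometry -------------------------------

struct Rect {
  double x0, y0, x1, y1;
  double cx() const { return 0.5 * (x0 + x1); }
  double cy() const { return 0.5 * (y0 + y1); }
};

struct ArenaParams {
  double size;
  Rect red, white;
  double agent_radius, wheel_base, contact_margin;
  double fov_half, view_range;
  double v_app, v_slow, v_back, v_exp, v_turn, v_max;
  double t_back, t_stop;
  double flash_duration;
  double lookahead, stall_timeout;
};

struct Pose {
  double x, y, th;
};

double rect_dist(const Rect& r, double x, double y) {
  double dx = std::max({r.x0 - x, 0.0, x - r.x1});
  double dy = std::max({r.y0 - y, 0.0, y - r.y1});
  return std::sqrt(dx * dx + dy * dy);
}

double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

ArenaParams arena_from_list(const List& cfg) {
  ArenaParams a;
  a.size = as<double>(cfg["size"]);
  double bw = as<double>(cfg["block_width"]);
  double bd = as<double>(cfg["block_depth"]);
  double mid = a.size / 2.0;
  // red on the far (north) wall, white on the near (south) wall
  a.red = Rect{mid - bw / 2, a.size - bd, mid + bw / 2, a.size};
  a.white = Rect{mid - bw / 2, 0.0, mid + bw / 2, bd};
  a.agent_radius = as<double>(cfg["agent_radius"]);
  a.wheel_base = as<double>(cfg["wheel_base"]);
  a.contact_margin = as<double>(cfg["contact_margin"]);
  a.fov_half = as<double>(cfg["fov_half_deg"]) * M_PI / 180.0;
  a.view_range = as<double>(cfg["view_range"]);
  a.v_app = as<double>(cfg["v_approach"]);
  a.v_slow = as<double>(cfg["v_slow"]);
  a.v_back = as<double>(cfg["v_back"]);
  a.v_exp = as<double>(cfg["v_explore"]);
  a.v_turn = as<double>(cfg["v_turn"]);
  a.v_max = as<double>(cfg["v_max"]);
  a.t_back = as<double>(cfg["t_back"]);
  a.t_stop = as<double>(cfg["t_stop"]);
  a.flash_duration = as<double>(cfg["flash_duration"]);
  a.lookahead = as<double>(cfg["lookahead"]);
  a.stall_timeout = as<double>(cfg["stall_timeout"]);
  return a;
}

// Differential-drive kinematics with wall clamping and block collision
// push-out (the arena is kinematic: no momentum, no friction).
void step_kinematics(Pose& p, double zl, double zr, double dt,
                     const ArenaParams& a) {
  double v = 0.5 * (zl + zr);
  double w = (zr - zl) / a.wheel_base;
  p.th = wrap_angle(p.th + w * dt);
  p.x += v * std::cos(p.th) * dt;
  p.y += v * std::sin(p.th) * dt;
  double r = a.agent_radius;
  p.x = std::min(a.size - r, std::max(r, p.x));
  p.y = std::min(a.size - r, std::max(r, p.y));
  // keep the body just outside the blocks (contact happens at the margin)
  const Rect* blocks[2] = {&a.red, &a.white};
  for (int b = 0; b < 2; ++b) {
    const Rect& rc = *blocks[b];
    double keep = r * 0.5;  // allow some overlap so contact registers
    if (p.x > rc.x0 - keep && p.x < rc.x1 + keep && p.y > rc.y0 - keep &&
        p.y < rc.y1 + keep) {
      // push out along the axis of least penetration
      double push[4] = {p.x - (rc.x0 - keep), (rc.x1 + keep) - p.x,
                        p.y - (rc.y0 - keep), (rc.y1 + keep) - p.y};
      int k = 0;
      for (int j = 1; j < 4; ++j)
        if (push[j] < push[k]) k = j;
      if (k == 0) p.x = rc.x0 - keep;
      else if (k == 1) p.x = rc.x1 + keep;
      else if (k == 2) p.y = rc.y0 - keep;
      else p.y = rc.y1 + keep;
    }
  }
}

bool in_contact(const Pose& p, const Rect& r, const ArenaParams& a) {
  return rect_dist(r, p.x, p.y) <= a.agent_radius + a.contact_margin;
}

bool block_visible(const Pose& p, const Rect& r, const ArenaParams& a) {
  double d = rect_dist(r, p.x, p.y);
  if (d > a.view_range) return false;
  double ang = std::atan2(r.cy() - p.y, r.cx() - p.x);
  return std::fabs(wrap_angle(ang - p.th)) <= a.fov_half;
}

// ------------------------- action subsystems (FSMs) ------------------------

enum Stage { ORIENT, APPROACH, BACKOFF, STOP, REAPPROACH };

struct InteractFsm {
  int stage = ORIENT;
  double timer = 0.0;
  double stage_time = 0.0;
  bool bumped_this_sequence = false;
  void reset() {
    stage = ORIENT;
    timer = 0.0;
    stage_time = 0.0;
    bumped_this_sequence = false;
  }
};

// Advance one block-interaction FSM; writes wheel command into (zl, zr) and
// flags bump / completion events for this step.
void interact_step(InteractFsm& f, const Pose& p, const Rect& block,
                   const ArenaParams& a, double dt, double& zl, double& zr,
                   bool& bump, bool& complete) {
  bump = false;
  complete = false;
  zl = zr = 0.0;
  double ang = std::atan2(block.cy() - p.y, block.cx() - p.x);
  double err = wrap_angle(ang - p.th);
  bool contact = in_contact(p, block, a);
  f.stage_time += dt;
  if (f.stage_time > a.stall_timeout) {
    f.reset();
    return;
  }
  switch (f.stage) {
    case ORIENT:
      if (std::fabs(err) < 0.15) {
        f.stage = APPROACH;
        f.stage_time = 0.0;
      } else {
        zl = err > 0 ? -a.v_turn : a.v_turn;
        zr = -zl;
      }
      break;
    case APPROACH:
      if (contact) {
        bump = true;
        f.bumped_this_sequence = true;
        f.stage = BACKOFF;
        f.timer = a.t_back;
        f.stage_time = 0.0;
      } else if (std::fabs(err) > 0.5) {
        f.stage = ORIENT;
        f.stage_time = 0.0;
      } else {
        zl = std::min(a.v_max, a.v_app * (1.0 - err));
        zr = std::min(a.v_max, a.v_app * (1.0 + err));
      }
      break;
    case BACKOFF:
      zl = zr = -a.v_back;
      f.timer -= dt;
      if (f.timer <= 0) {
        f.stage = STOP;
        f.timer = a.t_stop;
        f.stage_time = 0.0;
      }
      break;
    case STOP:
      f.timer -= dt;
      if (f.timer <= 0) {
        f.stage = REAPPROACH;
        f.stage_time = 0.0;
      }
      break;
    case REAPPROACH:
      if (contact) {
        complete = f.bumped_this_sequence;
        f.reset();
      } else {
        zl = std::min(a.v_max, a.v_slow * (1.0 - err));
        zr = std::min(a.v_max, a.v_slow * (1.0 + err));
      }
      break;
  }
}

struct ExploreFsm {
  double turn = 0.0;  // differential wheel command, redrawn with the
                      // explore salience (once per second)
  void redraw() { turn = R::runif(-2.0, 2.0); }
};

// Wander with obstacle avoidance: if the lookahead point would leave the
// arena or enter a block, rotate in place instead.
void explore_step(const ExploreFsm& f, const Pose& p, const ArenaParams& a,
                  double& zl, double& zr) {
  double lx = p.x + a.lookahead * std::cos(p.th);
  double ly = p.y + a.lookahead * std::sin(p.th);
  double r = a.agent_radius;
  bool blocked = lx < r || lx > a.size - r || ly < r || ly > a.size - r ||
                 rect_dist(a.red, lx, ly) < r || rect_dist(a.white, lx, ly) < r;
  if (blocked) {
    zl = a.v_turn;
    zr = -a.v_turn;
  } else {
    zl = a.v_exp - f.turn;
    zr = a.v_exp + f.turn;
  }
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported arena helpers (unit-testable single steps)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_step_kinematics(NumericVector pose, NumericVector z,
                                  double dt, List arena_cfg) {
  ArenaParams a = arena_from_list(arena_cfg);
  Pose p{pose[0], pose[1], pose[2]};
  step_kinematics(p, z[0], z[1], dt, a);
  return NumericVector::create(p.x, p.y, p.th);
}

// [[Rcpp::export]]
List cpp_perceive(NumericVector pose, List arena_cfg) {
  ArenaParams a = arena_from_list(arena_cfg);
  Pose p{pose[0], pose[1], pose[2]};
  return List::create(
      _["red_visible"] = block_visible(p, a.red, a),
      _["white_visible"] = block_visible(p, a.white, a),
      _["red_contact"] = in_contact(p, a.red, a),
      _["white_contact"] = in_contact(p, a.white, a),
      _["red_dist"] = rect_dist(a.red, p.x, p.y),
      _["white_dist"] = rect_dist(a.white, p.x, p.y));
}

// ---------------------------------------------------------------------------
// The session
// ---------------------------------------------------------------------------

// persist: list(weights, y_latent[2], seen_first[2], s_int[2],
//               ysq_d1[3], ysq_d2[3]) carried across days.
// schedule_kind: 0 = VI, 1 = FR1. contingent = FALSE during habituation.
// [[Rcpp::export]]
List cpp_run_session(List persist, List cfg, int schedule_kind, bool pda,
                     bool contingent, bool record_dense) {
  List net_cfg = cfg["network"], pred_cfg = cfg["prediction"],
       da_cfg = cfg["dopamine"], plast_cfg = cfg["plasticity"],
       arena_cfg = cfg["arena"], sched_cfg = cfg["schedule"],
       prot_cfg = cfg["protocol"];

  NetParams np = net_params_from_list(net_cfg);
  ArenaParams ar = arena_from_list(arena_cfg);
  CorticoStriatalWeights W = weights_from_list(persist["weights"]);
  PlasticityCoefficients A = coeffs_from_list(plast_cfg);

  double k = as<double>(pred_cfg["k"]);
  double gamma_b = as<double>(pred_cfg["gamma_b"]);
  double explore_max = as<double>(pred_cfg["explore_max"]);
  double explore_redraw = as<double>(pred_cfg["explore_redraw"]);

  double a_plus = as<double>(da_cfg["a_plus"]);
  double a_minus = as<double>(da_cfg["a_minus"]);
  double pulse_width = as<double>(da_cfg["pulse_width"]);
  double tau_snc = as<double>(da_cfg["tau"]);

  double tau_ratio = as<double>(plast_cfg["tau_ratio"]);
  double k_c = as<double>(plast_cfg["k_c"]);
  double eta = as<double>(plast_cfg["eta"]);
  double w_min = as<double>(plast_cfg["w_min"]);
  double w_max = as<double>(plast_cfg["w_max"]);
  double ysq_tau = as<double>(plast_cfg["ysq_tau"]);
  double window = as<double>(plast_cfg["window"]);

  double vi_mean = as<double>(sched_cfg["vi_mean"]);
  double session_length = as<double>(prot_cfg["session_length"]);

  NumericVector y_latent = clone(as<NumericVector>(persist["y_latent"]));
  LogicalVector seen_first = clone(as<LogicalVector>(persist["seen_first"]));
  NumericVector s_int = clone(as<NumericVector>(persist["s_int"]));
  NumericVector ysq_d1 = clone(as<NumericVector>(persist["ysq_d1"]));
  NumericVector ysq_d2 = clone(as<NumericVector>(persist["ysq_d2"]));

  RNGScope scope;

  NetState net;
  net_init(net);
  Pose pose{ar.size / 2.0, ar.size / 2.0, R::runif(-M_PI, M_PI)};

  InteractFsm fsm_red, fsm_white;
  ExploreFsm fsm_exp;
  fsm_exp.redraw();
  double s_explore = R::runif(0.0, explore_max);

  // VI schedule: armed once the drawn interval has elapsed
  double next_avail = R::rexp(vi_mean);

  double flash_until = -1.0;  // light off

  // phasic dopamine event state
  bool ev_active = false;
  double ev_t0 = 0.0, ev_ysc = 0.0, ev_ycancel = 0.0;
  double ev_theta_scale_d1 = 0.0, ev_theta_scale_d2 = 0.0;  // frozen <y^2>
  double ev_dmin = 0.0, ev_dmax = 0.0;
  double a_snc = 0.0;
  const double d_rest = snc_output(0.0);

  // outcome of the just-completed red interaction
  bool red_flashed = false;
  double red_y_star = 0.0;
  int ev_n = 0;
  std::vector<double> evt_t, evt_ysc, evt_ycan, evt_dmin, evt_dmax;

  // logs
  std::vector<double> it_time, it_block, it_flash, it_ystar_pre,
      it_ystar_post, it_sint, it_snov;
  std::vector<double> wt_snap;  // 12 per interaction
  std::vector<double> flash_times;
  std::vector<double> dn_t, dn_d, dn_sred, dn_bs1;
  std::vector<int> dn_sel;

  int n_steps = (int)std::lround(session_length / np.dt);
  int redraw_steps = std::max(1, (int)std::lround(explore_redraw / np.dt));

  // diagnostics
  int n_bump_red = 0, n_bump_white = 0;
  double t_vis_red = 0, t_vis_white = 0;
  double t_sel_exp = 0, t_sel_red = 0, t_sel_white = 0, t_sel_none = 0;

  double s[NCHAN], noise[NCHAN];

  for (int t = 0; t < n_steps; ++t) {
    double now = t * np.dt;

    if (t % redraw_steps == 0) {
      s_explore = R::runif(0.0, explore_max);
      fsm_exp.redraw();
    }

    // --- perception and salience --------------------------------------
    bool red_vis = block_visible(pose, ar.red, ar);
    bool white_vis = block_visible(pose, ar.white, ar);
    double s_nov_red = novelty_salience(y_latent[0]);
    s[CH_EXPLORE] = s_explore;
    s[CH_RED] = red_vis ? s_int[0] + s_nov_red : 0.0;
    s[CH_WHITE] = white_vis ? s_int[1] : 0.0;
    for (int i = 0; i < NCHAN; ++i)
      noise[i] = np.noise_sd > 0 ? R::rnorm(0.0, np.noise_sd) : 0.0;

    // --- network and selection ----------------------------------------
    net_step(net, s, noise, W, np);
    bool sel[NCHAN];
    int n_sel = 0;
    for (int i = 0; i < NCHAN; ++i) {
      sel[i] = net.bs.y[i] > np.phi;
      if (sel[i]) ++n_sel;
    }
    if (!std::isfinite(net.bs.a[0]))
      stop("non-finite network state: parameterization error");

    // --- subsystems and motor blending --------------------------------
    double zl = 0.0, zr = 0.0;
    bool bump_red = false, complete_red = false;
    bool bump_white = false, complete_white = false;
    if (n_sel > 0) {
      double zsl = 0.0, zsr = 0.0;
      if (sel[CH_EXPLORE]) {
        double el, er;
        explore_step(fsm_exp, pose, ar, el, er);
        zsl += el;
        zsr += er;
      }
      if (sel[CH_RED]) {
        double il, ir;
        interact_step(fsm_red, pose, ar.red, ar, np.dt, il, ir, bump_red,
                      complete_red);
        zsl += il;
        zsr += ir;
      } else {
        fsm_red.reset();
      }
      if (sel[CH_WHITE]) {
        double il, ir;
        interact_step(fsm_white, pose, ar.white, ar, np.dt, il, ir,
                      bump_white, complete_white);
        zsl += il;
        zsr += ir;
      } else {
        fsm_white.reset();
      }
      zl = zsl / n_sel;
      zr = zsr / n_sel;
    } else {
      fsm_red.reset();
      fsm_white.reset();
    }
    step_kinematics(pose, zl, zr, np.dt, ar);

    if (red_vis) t_vis_red += np.dt;
    if (white_vis) t_vis_white += np.dt;
    if (sel[CH_EXPLORE]) t_sel_exp += np.dt;
    if (sel[CH_RED]) t_sel_red += np.dt;
    if (sel[CH_WHITE]) t_sel_white += np.dt;
    if (n_sel == 0) t_sel_none += np.dt;
    if (bump_red) ++n_bump_red;
    if (bump_white) ++n_bump_white;

    // The outcome of a target interaction is evaluated when the
    // interaction sequence completes (the completing contact is the
    // operant response): schedule gate, flash, prediction read-out and the
    // phasic dopamine event all reference that moment.
    if (complete_red) {
      bool flash = false;
      if (contingent) {
        if (schedule_kind == 1) {
          flash = true;
        } else if (now >= next_avail) {
          flash = true;
          next_avail = now + R::rexp(vi_mean);
        }
      }
      red_y_star = y_latent[0];  // phasic read-out of the latent prediction
      red_flashed = flash;
      if (flash) {
        flash_until = now + ar.flash_duration;
        flash_times.push_back(now);
      }
      // dopamine event: burst on an unpredicted flash, dip on an omitted
      // but partially predicted flash
      double y_f = flash ? 1.0 : 0.0;
      double ysc = sc_response(y_f, red_y_star);
      double ycan = cancel_signal(y_f, red_y_star);
      if (pda && (ysc > 0.0 || ycan > 0.0)) {
        ev_active = true;
        ev_t0 = now;
        ev_ysc = ysc;
        ev_ycancel = ycan;
        ev_theta_scale_d1 = ysq_d1[CH_RED];
        ev_theta_scale_d2 = ysq_d2[CH_RED];
        ev_dmin = ev_dmax = snc_output(a_snc);
        ev_n += 1;
      }
    }

    // --- dopamine dynamics --------------------------------------------
    double d = d_rest;
    if (pda) {
      double I_snc = 0.0;
      if (ev_active) {
        double y_sc_t = triangular_pulse(now, ev_t0, pulse_width, ev_ysc);
        double y_can_t =
            triangular_pulse(now, ev_t0, pulse_width, ev_ycancel);
        I_snc = snc_input(y_sc_t, y_can_t, a_plus, a_minus);
      }
      a_snc = integrate_unit(a_snc, I_snc, np.dt, tau_snc);
      d = snc_output(a_snc);
      if (ev_active) {
        ev_dmin = std::min(ev_dmin, d);
        ev_dmax = std::max(ev_dmax, d);
        if (now - ev_t0 > window) {
          ev_active = false;
          evt_t.push_back(ev_t0);
          evt_ysc.push_back(ev_ysc);
          evt_ycan.push_back(ev_ycancel);
          evt_dmin.push_back(ev_dmin);
          evt_dmax.push_back(ev_dmax);
        }
      }
    }

    // --- plasticity (gated to the window after a phasic event) --------
    if (ev_active && pda) {
      double x_m = net.mc.y[CH_RED], x_s = net.ssc.y[CH_RED];
      double y1 = net.d1.y[CH_RED], y2 = net.d2.y[CH_RED];
      double c1 = c_bcm(d, true, A, tau_ratio, k_c);
      double c2 = c_bcm(d, false, A, tau_ratio, k_c);
      double th1 = theta_bcm(ev_theta_scale_d1, c1);
      double th2 = theta_bcm(ev_theta_scale_d2, c2);
      W.m_d1[CH_RED] =
          weight_update(W.m_d1[CH_RED], x_m, y1, th1, eta, np.dt, w_min, w_max);
      W.s_d1[CH_RED] =
          weight_update(W.s_d1[CH_RED], x_s, y1, th1, eta, np.dt, w_min, w_max);
      W.m_d2[CH_RED] =
          weight_update(W.m_d2[CH_RED], x_m, y2, th2, eta, np.dt, w_min, w_max);
      W.s_d2[CH_RED] =
          weight_update(W.s_d2[CH_RED], x_s, y2, th2, eta, np.dt, w_min, w_max);
    }

    // --- <y^2> trackers ------------------------------------------------
    for (int i = 0; i < NCHAN; ++i) {
      ysq_d1[i] = update_ysq(ysq_d1[i], net.d1.y[i], np.dt, ysq_tau);
      ysq_d2[i] = update_ysq(ysq_d2[i], net.d2.y[i], np.dt, ysq_tau);
    }

    // --- completed interactions ---------------------------------------
    if (complete_red) {
      bool flashed = red_flashed;
      double y_post =
          update_prediction(y_latent[0], flashed, seen_first[0], k);
      if (flashed) seen_first[0] = true;
      double y_pre = red_y_star;
      y_latent[0] = y_post;
      it_time.push_back(now);
      it_block.push_back(1);
      it_flash.push_back(flashed ? 1 : 0);
      it_ystar_pre.push_back(y_pre);
      it_ystar_post.push_back(y_post);
      it_sint.push_back(s_int[0]);
      it_snov.push_back(s_nov_red);
      s_int[0] *= gamma_b;  // within-day habituation, per completed bout
      const double* wp[4] = {W.m_d1, W.s_d1, W.m_d2, W.s_d2};
      for (int g = 0; g < 4; ++g)
        for (int i = 0; i < NCHAN; ++i) wt_snap.push_back(wp[g][i]);
    }
    if (complete_white) {
      it_time.push_back(now);
      it_block.push_back(2);
      it_flash.push_back(0);
      it_ystar_pre.push_back(y_latent[1]);
      it_ystar_post.push_back(y_latent[1]);
      it_sint.push_back(s_int[1]);
      it_snov.push_back(novelty_salience(y_latent[1]));
      s_int[1] *= gamma_b;
      const double* wp[4] = {W.m_d1, W.s_d1, W.m_d2, W.s_d2};
      for (int g = 0; g < 4; ++g)
        for (int i = 0; i < NCHAN; ++i) wt_snap.push_back(wp[g][i]);
    }

    if (flash_until > 0 && now > flash_until) flash_until = -1.0;

    if (record_dense) {
      dn_t.push_back(now);
      dn_d.push_back(d);
      dn_sred.push_back(s[CH_RED]);
      dn_bs1.push_back(net.bs.y[CH_RED]);
      int mask = 0;
      for (int i = 0; i < NCHAN; ++i)
        if (sel[i]) mask |= (1 << i);
      dn_sel.push_back(mask);
    }
  }

  if (ev_active) {
    evt_t.push_back(ev_t0);
    evt_ysc.push_back(ev_ysc);
    evt_ycan.push_back(ev_ycancel);
    evt_dmin.push_back(ev_dmin);
    evt_dmax.push_back(ev_dmax);
  }

  int n_int = (int)it_time.size();
  NumericMatrix wts(n_int, 12);
  for (int r = 0; r < n_int; ++r)
    for (int c = 0; c < 12; ++c) wts(r, c) = wt_snap[r * 12 + c];

  List persist_out = List::create(
      _["weights"] = weights_to_list(W), _["y_latent"] = y_latent,
      _["seen_first"] = seen_first, _["s_int"] = s_int,
      _["ysq_d1"] = ysq_d1, _["ysq_d2"] = ysq_d2);

  List dense = R_NilValue;
  if (record_dense)
    dense = List::create(_["time"] = dn_t, _["d"] = dn_d,
                         _["s_red"] = dn_sred, _["y_bs_red"] = dn_bs1,
                         _["selected_mask"] = dn_sel);

  return List::create(
      _["interactions"] = List::create(
          _["time"] = it_time, _["block"] = it_block, _["flash"] = it_flash,
          _["y_star_pre"] = it_ystar_pre, _["y_star_post"] = it_ystar_post,
          _["s_int"] = it_sint, _["s_nov"] = it_snov),
      _["weight_snapshots"] = wts, _["flash_times"] = flash_times,
      _["dopamine_events"] = List::create(
          _["time"] = evt_t, _["y_sc"] = evt_ysc, _["y_cancel"] = evt_ycan,
          _["d_min"] = evt_dmin, _["d_max"] = evt_dmax),
      _["diagnostics"] = List::create(
          _["n_bump_red"] = n_bump_red, _["n_bump_white"] = n_bump_white,
          _["t_visible_red"] = t_vis_red, _["t_visible_white"] = t_vis_white,
          _["t_selected_explore"] = t_sel_exp,
          _["t_selected_red"] = t_sel_red,
          _["t_selected_white"] = t_sel_white,
          _["t_selected_none"] = t_sel_none),
      _["persist"] = persist_out, _["dense"] = dense);
}
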