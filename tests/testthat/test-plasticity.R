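test_that("the dopamine mixing function is exact at its anchor points", {
  expect_equal(alpha_mix(0), 0)
  expect_equal(alpha_mix(0.25), 0.5)
  expect_equal(alpha_mix(1), 0.8)
  expect_true(all(diff(alpha_mix(seq(0, 5, by = 0.1))) > 0))
  expect_error(alpha_mix(-0.1), "non-negative")
})

test_that("coefficient blending interpolates between the lo and hi values", {
  expect_equal(blend_coefficient(2, -1, 0), -1)
  expect_equal(blend_coefficient(2, -1, 0.25), 0.5)
  expect_equal(blend_coefficient(2, -1, 1e6), 2, tolerance = 1e-4)
})

test_that("C_BCM has the receptor-specific sign structure", {
  co <- default_config()$plasticity
  expect_gt(c_bcm(0, "D1", co), 0)     # low dopamine: D1 depression-prone
  expect_lt(c_bcm(0, "D2", co), 0)     # low dopamine: D2 potentiation-prone
  expect_lt(c_bcm(2, "D1", co), 0)     # high dopamine: D1 potentiation
  expect_gt(c_bcm(2, "D2", co), 0)     # high dopamine: D2 depression
})

test_that("theta scales with tracked activity and C", {
  expect_equal(theta_bcm(0, -2), 0)
  expect_equal(theta_bcm(0.25, -2), -0.5)
  expect_equal(theta_bcm(0.5, 3) / theta_bcm(0.25, 3), 2)
  expect_error(theta_bcm(-1, 2), "non-negative")
})

test_that("BCM zero crossing: dw = 0 exactly when y = theta", {
  w0 <- 0.7
  for (theta in c(-0.5, 0.2, 0.9)) {
    y <- theta
    w1 <- weight_update(w0, x = 0.8, y = y, theta = theta, eta = 0.1,
                        dt = 0.01)
    expect_identical(w1, w0)
  }
  # either factor zero also freezes the weight
  expect_identical(weight_update(w0, 0, 0.5, -1, 0.1, 0.01), w0)
  expect_identical(weight_update(w0, 0.5, 0, -1, 0.1, 0.01), w0)
})

test_that("sign of the update follows y(y - theta)x and bounds clip", {
  up <- weight_update(0.5, 0.8, 0.6, -0.5, 1, 0.01)
  expect_gt(up, 0.5)                                  # LTP when theta < 0 < y
  dn <- weight_update(0.5, 0.8, 0.3, 0.9, 1, 0.01)
  expect_lt(dn, 0.5)                                  # LTD when y < theta
  expect_equal(weight_update(0.01, 1, 0.1, 5, 10, 1), 0)        # floor
  expect_equal(weight_update(1.99, 1, 1, -5, 10, 1, w_max = 2), 2)  # cap
})

test_that("the <y^2> tracker is an EMA with fixed point y^2", {
  tr <- 0
  for (i in 1:20000) tr <- update_ysq(tr, 0.6, 0.01, ysq_tau = 5)
  expect_equal(tr, 0.36, tolerance = 1e-6)
  tr0 <- 0
  n <- 500  # exactly one time constant at dt = 0.01, tau = 5
  for (i in 1:n) tr0 <- update_ysq(tr0, 1, 0.01, 5)
  expect_equal(tr0, 1 - (1 - 0.01 / 5)^n, tolerance = 1e-12)
  expect_equal(1 - (1 - 0.01 / 5)^n, 1 - exp(-1), tolerance = 1e-3)
})

# integrate the rule over one phasic event using the package's own dopamine
# transient, with constant pre/post rates and the tracker frozen at onset
event_dw <- function(y_f, y_star, receptor, y = 0.9, x = 0.85, ysq = y^2,
                     cfg = default_config()) {
  tr <- dopamine_transient(y_f, y_star, cfg, duration = cfg$plasticity$window)
  co <- cfg$plasticity
  w <- 1
  for (d in tr$d) {
    th <- theta_bcm(ysq, c_bcm(d, receptor, co))
    w <- weight_update(w, x, y, th, co$eta, cfg$network$dt,
                       w_min = 0, w_max = 10)
  }
  w - 1
}

test_that("dip-dominated events depress D1 and potentiate D2", {
  dw1 <- event_dw(0, 0.4, "D1")
  dw2 <- event_dw(0, 0.4, "D2")
  expect_lt(dw1, 0)
  expect_gt(dw2, 0)
})

test_that("burst-dominated events potentiate D1 strongly", {
  dw1 <- event_dw(1, 0.2, "D1")
  expect_gt(dw1, 0)
  # larger prediction errors potentiate more
  expect_gt(dw1, event_dw(1, 0.6, "D1"))
  # small late-stage bursts sit on the depression side for D1
  expect_lt(event_dw(1, 0.95, "D1"), 0)
})

test_that("motor and sensory trajectories mirror each other in form", {
  cfg <- ad_short_cfg
  set.seed(9)
  p <- initial_persist(ad_weights, cfg)
  for (day in 1:5) {
    out <- run_session(p, day, cfg, "FR1", pda = TRUE, contingent = day > 2)
    p <- out$persist
  }
  snaps <- out$weight_snapshots
  if (nrow(snaps) > 3) {
    dm <- diff(snaps[, "m_d1.red"])
    ds <- diff(snaps[, "s_d1.red"])
    nz <- dm != 0 & ds != 0
    if (any(nz)) expect_true(all(sign(dm[nz]) == sign(ds[nz])))
  }
  # sensory weights can only be non-negative (start 0, LTP-grown)
  expect_true(all(snaps[, grepl("^s_", colnames(snaps))] >= 0))
})
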