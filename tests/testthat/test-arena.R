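test_that("differential-drive kinematics: straight, rotate, wall clamp", {
  arena <- ad_cfg$arena
  p0 <- c(30, 30, 0)
  p1 <- step_kinematics(p0, c(5, 5), 1, arena)
  expect_equal(p1, c(35, 30, 0))
  p2 <- step_kinematics(p0, c(-3, 3), 0.5, arena)
  expect_equal(p2[1:2], c(30, 30))
  expect_gt(p2[3], 0)  # pure rotation
  # cannot escape through a wall
  p <- c(58, 30, 0)
  for (i in 1:200) p <- step_kinematics(p, c(10, 10), 0.1, arena)
  expect_lte(p[1], arena$size - arena$agent_radius + 1e-9)
})

test_that("perception respects the field-of-view cone and range", {
  arena <- ad_cfg$arena
  # mid-arena facing north: red (north wall) visible, white not
  v <- perceive(c(30, 30, pi / 2), arena)
  expect_true(v$red_visible)
  expect_false(v$white_visible)
  v2 <- perceive(c(30, 30, -pi / 2), arena)
  expect_false(v2$red_visible)
  expect_true(v2$white_visible)
  # facing a side wall: neither block in the cone
  v3 <- perceive(c(30, 30, 0), arena)
  expect_false(v3$red_visible)
  expect_false(v3$white_visible)
  # adjacent to the red block and facing it: contact
  v4 <- perceive(c(30, 51, pi / 2), arena)
  expect_true(v4$red_contact)
})

test_that("motor blending averages selected commands", {
  expect_equal(blend_motors(list()), c(0, 0))
  expect_equal(blend_motors(list(c(4, 2))), c(4, 2))
  expect_equal(blend_motors(list(c(4, 4), c(-4, -4))), c(0, 0))
  expect_equal(blend_motors(list(c(2, 0), c(0, 2), c(1, 1))), c(1, 1))
})

test_that("the schedule gate: FR1 always, VI only when armed", {
  set.seed(1)
  fr <- schedule_state("FR1")
  for (t in c(0, 1, 500)) expect_true(schedule_gate(fr, t)$flash)
  vi <- schedule_state("VI", vi_mean = 120, t = 0)
  expect_gt(vi$next_avail, 0)
  # premature bump: no flash, schedule unchanged
  res <- schedule_gate(vi, vi$next_avail - 1)
  expect_false(res$flash)
  expect_equal(res$schedule$next_avail, vi$next_avail)
  # armed bump: flash and re-arm later
  res2 <- schedule_gate(vi, vi$next_avail + 1)
  expect_true(res2$flash)
  expect_gt(res2$schedule$next_avail, vi$next_avail + 1)
  expect_error(schedule_state("VI", vi_mean = -1), "positive")
})

test_that("VI inter-availability intervals are exponential with mean 120", {
  set.seed(8)
  s <- schedule_state("VI")
  draws <- replicate(4000, {
    r <- schedule_gate(s, s$next_avail + 1)
    r$schedule$next_avail - (s$next_avail + 1)
  })
  expect_equal(mean(draws), 120, tolerance = 0.1 * 120)
  expect_equal(sd(draws), 120, tolerance = 0.15 * 120)
})

test_that("under FR1 every completed red interaction flashes", {
  out <- run_days(3, "FR1", pda = TRUE, seed = 3, cfg = ad_short_cfg,
                  hab_days = 2)
  it <- out$interactions
  red <- it[it$block == 1, ]
  expect_equal(length(out$flash_times), nrow(red))
  expect_true(all(red$flash == 1))
  # white bumps never flash
  expect_true(all(it$flash[it$block == 2] == 0))
})

test_that("under VI the flash rate is bounded by the schedule", {
  outs <- run_days(5, "VI", pda = TRUE, seed = 4, cfg = ad_short_cfg,
                   hab_days = 2, keep = "all")
  for (day in 3:5) {
    n_flash <- length(outs[[day]]$flash_times)
    expect_lte(n_flash, ceiling(ad_short_cfg$protocol$session_length / 120) + 2)
    # flashed interactions are a subset of red completions
    it <- outs[[day]]$interactions
    expect_lte(n_flash, sum(it$block == 1))
  }
})

test_that("habituation sessions deliver no flashes and rest-level dopamine", {
  out <- run_days(2, "VI", pda = TRUE, seed = 5, cfg = ad_short_cfg,
                  hab_days = 2)
  expect_length(out$flash_times, 0)
  expect_equal(nrow(out$dopamine_events), 0)
})

test_that("with phasic dopamine disabled no dopamine events occur", {
  out <- run_days(4, "FR1", pda = FALSE, seed = 6, cfg = ad_short_cfg,
                  hab_days = 2)
  expect_equal(nrow(out$dopamine_events), 0)
  # and the weights stay exactly at their initial values
  expect_identical(out$persist$weights$m_d1, ad_weights$m_d1)
  expect_identical(out$persist$weights$m_d2, ad_weights$m_d2)
})

test_that("session logs span the session and habituate salience per bout", {
  out <- run_days(1, "VI", pda = TRUE, seed = 7, cfg = ad_short_cfg,
                  hab_days = 2)
  it <- out$interactions
  expect_true(all(it$time >= 0 & it$time < ad_short_cfg$protocol$session_length))
  for (b in 1:2) {
    si <- it$s_int[it$block == b]
    if (length(si) > 1) {
      ratios <- si[-1] / si[-length(si)]
      expect_equal(ratios, rep(0.95, length(ratios)), tolerance = 1e-10)
    }
  }
})
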