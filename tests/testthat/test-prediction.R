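test_that("prediction updates follow the recursive flash/omission rules", {
  expect_equal(update_prediction(0, "flash", seen_first = FALSE), 0.2)
  expect_equal(update_prediction(0.2, "flash", seen_first = TRUE), 0.24)
  expect_equal(update_prediction(0.24, "omission"), 0.228)
  # an omission with no prediction leaves it untouched
  expect_equal(update_prediction(0, "omission"), 0)
  expect_error(update_prediction(0.5, "flash", k = 1.5), "k must be")
})

test_that("n consecutive flashes after the first give y = 1 - 0.8 k^n", {
  k <- 0.95
  y <- update_prediction(0, "flash", seen_first = FALSE, k = k)
  for (n in 1:60) {
    y <- update_prediction(y, "flash", seen_first = TRUE, k = k)
    expect_equal(y, 1 - 0.8 * k^n, tolerance = 1e-12)
  }
})

test_that("the latent prediction stays in [0,1] and moves monotonically", {
  set.seed(3)
  y <- 0.2
  for (i in 1:500) {
    flash <- runif(1) < 0.3
    y2 <- update_prediction(y, if (flash) "flash" else "omission")
    expect_true(y2 >= 0 && y2 <= 1)
    if (flash) expect_gt(y2, y) else expect_lte(y2, y)
    y <- y2
  }
})

test_that("novelty salience is a symmetric tent map peaking at 0.5", {
  expect_equal(novelty_salience(0.5), 0.5)
  expect_equal(novelty_salience(c(0, 1)), c(0, 0))
  expect_equal(novelty_salience(0.2), 0.2)
  ys <- seq(0, 1, by = 0.05)
  expect_equal(novelty_salience(ys), novelty_salience(1 - ys))
  expect_true(all(novelty_salience(ys) <= 0.5))
  expect_identical(phasic_prediction(0.24), 0.24)
})

test_that("within-day habituation is geometric per completed interaction", {
  expect_equal(habituate_within_day(0.45), 0.4275)
  expect_equal(habituate_within_day(0.3, gamma_b = 1), 0.3)
  s <- 0.45
  for (j in 1:10) s <- habituate_within_day(s)
  expect_equal(s, 0.45 * 0.95^10)
})

test_that("across-day dishabituation recovers above the within-day floor", {
  d2 <- dishabituate_across_days(0.45)
  expect_equal(d2, 0.4275)
  # ten within-day decrements leave less salience than the next day's start
  expect_gt(d2, 0.45 * 0.95^10)
  expect_equal(dishabituate_across_days(0.3, gamma_a = 1), 0.3)
})

test_that("total salience adds intrinsic and novelty terms", {
  expect_equal(total_salience(0.4275, 0.3), 0.7275)
  expect_equal(total_salience(0.3, 0), 0.3)
  # a never-flashed block has zero prediction hence zero novelty salience
  expect_equal(novelty_salience(0), 0)
})

test_that("explore salience has the printed uniform moments", {
  set.seed(42)
  x <- explore_salience(1e5)
  expect_true(all(x >= 0 & x <= 0.8))
  expect_equal(mean(x), 0.4, tolerance = 0.003)
  expect_equal(sd(x), 0.8 / sqrt(12), tolerance = 0.01)
})

test_that("the prediction persists across day boundaries in the engine", {
  cfg <- ad_short_cfg
  set.seed(5)
  p <- initial_persist(ad_weights, cfg)
  y_end <- NA
  for (day in 1:4) {
    out <- run_session(p, day, cfg, "FR1", pda = TRUE, contingent = day > 2)
    p <- out$persist
    if (day == 3) y_end <- p$y_latent[1]
  }
  it <- out$interactions
  red <- it[it$block == 1, ]
  if (nrow(red)) {
    # day 4's first red interaction reads out the day-3 carry-over
    expect_equal(red$y_star_pre[1], y_end, tolerance = 1e-12)
  }
  expect_gte(p$y_latent[1], y_end)  # FR flashes only move it up
  expect_equal(p$y_latent[2], 0)    # white never flashes
})
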