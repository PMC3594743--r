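test_that("leaky integrator steps and converges as the unit equation demands", {
  expect_equal(integrate_unit(0, 0, 0.01, 0.04), 0)
  expect_equal(integrate_unit(0, 1, 0.01, 0.04), 0.25)
  # held input: geometric approach to the fixed point a* = I
  a <- 0
  for (i in 1:2000) a <- integrate_unit(a, 1, 0.01, 0.04)
  expect_equal(a, 1, tolerance = 1e-9)
  expect_error(integrate_unit(0, 1, 0.05, 0.04), "stability")
  expect_error(integrate_unit(0, 1, -0.01, 0.04), "stability")
})

test_that("piecewise-linear squashing has the three branches", {
  expect_equal(squash_rate(0.2, eps = 0.2), 0)
  expect_equal(squash_rate(0.7, eps = 0.2), 0.5)
  expect_equal(squash_rate(2.0, eps = 0.2), 1)
  expect_equal(squash_rate(-1, eps = -0.25), 0)
  expect_equal(squash_rate(0, eps = -0.25), 0.25)  # tonic rate at rest
  expect_equal(squash_rate(c(-1, 0.5, 3), eps = 0),
               c(0, 0.5, 1))
})

test_that("tonic dopamine scales D1 up and D2 down", {
  expect_equal(effective_cortico_striatal_weight(1, 0.2, "D1"), 1.2)
  expect_equal(effective_cortico_striatal_weight(1, 0.2, "D2"), 0.8)
  expect_equal(effective_cortico_striatal_weight(0.7, 0, "D1"), 0.7)
  expect_equal(effective_cortico_striatal_weight(0.7, 0, "D2"), 0.7)
  expect_error(effective_cortico_striatal_weight(-1, 0.2, "D1"),
               "non-negative")
})

test_that("rest state: GPi/SNr tonically active, nothing selected", {
  r <- settle_network(c(0, 0, 0), ad_weights, ad_cfg$network)
  expect_true(all(r$y_gpi > 0.05))
  expect_true(all(r$y_bs < ad_cfg$network$phi))
  expect_length(r$selected, 0)
})

test_that("the dominant salience is selected and losers are suppressed", {
  for (s in list(c(0.8, 0.4, 0), c(0.4, 0.8, 0), c(0, 0.3, 0.6))) {
    r <- settle_network(s, ad_weights, ad_cfg$network)
    expect_identical(r$selected, which.max(s))
    # winner has the channel-wise minimum basal-ganglia output
    expect_equal(which.min(r$y_gpi), which.max(s))
  }
})

test_that("channel permutation symmetry holds", {
  s <- c(0.7, 0.35, 0.1)
  r1 <- settle_network(s, ad_weights, ad_cfg$network)
  perm <- c(3, 1, 2)
  r2 <- settle_network(s[perm], ad_weights, ad_cfg$network)
  expect_equal(r2$y_bs, r1$y_bs[perm], tolerance = 1e-10)
  expect_equal(r2$y_gpi, r1$y_gpi[perm], tolerance = 1e-10)
})

test_that("saliences separated by >= 0.2 never co-select (sampled grid)", {
  for (s1 in c(0.3, 0.5, 0.7)) for (gap in c(0.2, 0.3, 0.5)) {
    s2 <- s1 + gap
    if (s2 > 1) next
    sel <- settle_network(c(s1, s2, 0), ad_weights, ad_cfg$network)$selected
    expect_true(all(sel == 2L),
                info = sprintf("s=(%.1f,%.1f) selected %s", s1, s2,
                               paste(sel, collapse = ",")))
  }
})

test_that("raising a competitor's salience mid-run switches the selection", {
  st <- step_network(network_rest_state(), c(0.8, 0.3, 0), ad_weights,
                     ad_cfg$network, duration = 1)
  expect_identical(select_actions(st$bs$y, 0.5), 1L)
  st2 <- step_network(st, c(0.3, 0.8, 0), ad_weights, ad_cfg$network,
                      duration = 1)
  expect_identical(select_actions(st2$bs$y, 0.5), 2L)
})

test_that("equal saliences resolve to a single channel under noise", {
  set.seed(11)
  st <- step_network(network_rest_state(), c(0.6, 0.6, 0), ad_weights,
                     ad_cfg$network, duration = 3, noise_sd = 0.02)
  sel <- select_actions(st$bs$y, 0.5)
  expect_true(length(sel) >= 1)
  expect_true(abs(st$bs$y[1] - st$bs$y[2]) > 0.05)  # symmetry broken
})

test_that("select_actions thresholds brainstem output", {
  expect_identical(select_actions(c(0.6, 0.3, 0.1)), 1L)
  expect_identical(select_actions(c(0.2, 0.3, 0.1)), integer(0))
  expect_identical(select_actions(c(0.6, 0.7, 0.1)), c(1L, 2L))
})

test_that("calibration yields positive motor weights, zero sensory weights", {
  expect_true(all(ad_weights$m_d1 > 0))
  expect_true(all(ad_weights$m_d2 > 0))
  expect_identical(ad_weights$s_d1, rep(0, 3))
  expect_identical(ad_weights$s_d2, rep(0, 3))
  expect_true(attr(ad_weights, "battery")$pass)
})

test_that("squashed outputs stay in [0,1] over a long noisy run", {
  set.seed(7)
  st <- network_rest_state()
  for (i in 1:20) {
    s <- runif(3, 0, 1)
    st <- step_network(st, s, ad_weights, ad_cfg$network, duration = 0.5,
                       noise_sd = 0.05)
    ys <- unlist(lapply(st, `[[`, "y"))
    expect_true(all(ys >= 0 & ys <= 1))
  }
})
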