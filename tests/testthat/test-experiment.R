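test_that("r_peak rounds half-up and handles degenerate input", {
  expect_identical(r_peak(c(10, 20, 15), c(5, 5, 5)), 4L)
  expect_identical(r_peak(c(5, 5), c(5, 5)), 1L)
  expect_identical(r_peak(c(7, 3), c(2, 2)), 4L)  # 3.5 rounds half-up
  expect_identical(r_peak(c(4, 2), c(0, 0)), NA_integer_)
})

test_that("experiments are bitwise reproducible and structured", {
  ex1 <- run_experiment(ad_short_cfg, "VI", pda = TRUE, n_runs = 2,
                        base_seed = 21, weights = ad_weights)
  ex2 <- run_experiment(ad_short_cfg, "VI", pda = TRUE, n_runs = 2,
                        base_seed = 21, weights = ad_weights)
  expect_identical(ex1$responses, ex2$responses)
  expect_identical(ex1$weights, ex2$weights)
  expect_identical(ex1$events, ex2$events)
  # different seeds diverge
  ex3 <- run_experiment(ad_short_cfg, "VI", pda = TRUE, n_runs = 2,
                        base_seed = 22, weights = ad_weights)
  expect_false(identical(ex1$responses, ex3$responses))
  # schema
  expect_named(ex1$responses, c("run", "day", "phase", "epoch", "block",
                                "count"))
  expect_setequal(unique(ex1$weights$receptor), c("D1", "D2"))
  expect_setequal(unique(ex1$weights$source), c("motor", "sensory"))
  expect_length(ex1$failed_runs, 0)
  expect_s3_class(ex1, "ad_experiment")
  expect_output(print(ex1), "r_peak")
})

test_that("epoch counts partition the daily totals", {
  ex <- run_experiment(ad_short_cfg, "FR1", pda = TRUE, n_runs = 2,
                       base_seed = 31, weights = ad_weights)
  resp <- ex$responses
  daily <- aggregate(count ~ run + day + block, resp, sum)
  byep <- aggregate(count ~ run + day + block + epoch, resp, sum)
  for (i in seq_len(nrow(daily))) {
    sel <- byep$run == daily$run[i] & byep$day == daily$day[i] &
      byep$block == daily$block[i]
    expect_equal(sum(byep$count[sel]), daily$count[i])
  }
  ec <- epoch_counts(ex, "red")
  expect_length(ec, 3)
  expect_true(all(ec >= 0))
  dc <- daily_counts(ex)
  rc <- dc[dc$phase == "RC", ]
  # epoch means partition the mean daily totals
  expect_equal(sum(epoch_counts(ex, "red")), mean(rc$active),
               tolerance = 1e-9)
  expect_equal(sum(epoch_counts(ex, "white")), mean(rc$inactive),
               tolerance = 1e-9)
})

test_that("the habituation symmetry test behaves as a two-sided p-value", {
  ex <- run_experiment(ad_short_cfg, "VI", pda = FALSE, n_runs = 3,
                       base_seed = 41, weights = ad_weights)
  ht <- habituation_symmetry_test(ex)
  expect_true(ht$p_value >= 0 && ht$p_value <= 1)
  expect_length(ht$active, 3)
})

test_that("output files carry metadata and are reproducible byte-for-byte", {
  ex <- run_experiment(ad_short_cfg, "VI", pda = TRUE, n_runs = 2,
                       base_seed = 51, weights = ad_weights)
  d1 <- file.path(tempdir(), "out1")
  d2 <- file.path(tempdir(), "out2")
  write_experiment(ex, d1)
  write_experiment(ex, d2)
  for (f in c("responses.csv", "weights.csv", "events.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  hdr <- readLines(file.path(d1, "responses.csv"), n = 1)
  expect_match(hdr, "config=")
  expect_match(hdr, "seed=")
})

test_that("mean weight trajectories interpolate to a common grid", {
  ex <- run_experiment(ad_short_cfg, "FR1", pda = TRUE, n_runs = 2,
                       base_seed = 61, weights = ad_weights)
  tr <- mean_weight_trajectory(ex, "D1", "motor", "red", grid_step = 60)
  total <- (ad_short_cfg$protocol$days_habituation +
              ad_short_cfg$protocol$days_rc) *
    ad_short_cfg$protocol$session_length
  expect_equal(range(tr$time), c(0, total))
  expect_false(any(is.na(tr$weight)))
  expect_equal(tr$weight[1], ad_weights$m_d1[2], tolerance = 1e-9)
  ws <- weight_change_summary(ex)
  expect_equal(nrow(ws), 4)
})
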