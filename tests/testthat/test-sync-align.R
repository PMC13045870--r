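test_that("velocity is the finite difference with a NaN first sample", {
  v <- compute_velocity(cbind(c(0, 1), c(0, 5)))
  expect_true(is.nan(v[1, 2]))
  expect_equal(unname(v[2, 2]), 5)
  v2 <- compute_velocity(cbind(0:4, rep(3, 5)))
  expect_true(is.nan(v2[1, 2]))
  expect_equal(unname(v2[-1, 2]), rep(0, 4))
  expect_error(compute_velocity(cbind(c(0, 0.5, 0.5), c(0, 1, 2))),
               "duplicate")
  # independent elementwise recomputation on a random monotone series
  set.seed(31)
  t <- cumsum(runif(200, 0.001, 0.01))
  x <- cumsum(rnorm(200, 0.05, 0.02))
  v3 <- compute_velocity(cbind(t, x))
  for (i in 2:200)
    expect_equal(unname(v3[i, 2]), (x[i] - x[i - 1]) / (t[i] - t[i - 1]))
  expect_equal(unname(v3[, 1]), t)
})

test_that("frame triggers merge with radii on a shared time column", {
  m <- merge_frames(matrix(numeric(0), ncol = 2),
                    data.frame(frame = integer(0), radius = numeric(0)))
  expect_equal(nrow(m$frame_combined), 0)
  trig <- cbind(c(0.1, 0.2, 0.3), 1:3)
  rad <- data.frame(frame = c(1, 3), radius = c(10, 12))
  m2 <- merge_frames(trig, rad)
  expect_equal(m2$frame_combined[, 1], m2$pupil_radius_combined[, 1])
  expect_equal(diff(m2$frame_combined[, 1]), rep(0.1, 2))
  expect_equal(m2$pupil_radius_combined[, 2], c(10, NaN, 12))
})

test_that("TTL edges are reported at the next 300 Hz tick", {
  p <- 1 / 300
  s <- sample_ttl(c(0, p, 2 * p), p)
  expect_equal(s$latency, rep(0, 3)) # edges exactly on ticks
  s2 <- sample_ttl(p + 1e-5, p)
  expect_equal(s2$latency, p - 1e-5, tolerance = 1e-9)
  set.seed(17)
  edges <- runif(10000, 0, 100)
  lat <- sample_ttl(edges, p)$latency
  expect_true(all(lat >= 0 & lat < p + 1e-12))
})

test_that("clock discrepancy vanishes without jitter and quantization", {
  cfg <- small_two_choice_cfg(max_rewards = 3L)
  rig <- rig_clocks(
    mcu = clock_spec(offset = 5, jitter_sd_ms = 0, drift_ppm = 0,
                     period_ms = 1e-6),
    program = clock_spec(jitter_sd_ms = 0, period_ms = 1e-6))
  raw <- run_session(cfg, agent_policy(d_true = 3), rig = rig, seed = 8)
  cd <- clock_discrepancy(raw)
  # a pure offset cancels in epoch durations
  expect_equal(cd$mean_ms, 0, tolerance = 1e-6)
  expect_equal(cd$max_ms, 0, tolerance = 1e-6)
})

test_that("sub-millisecond jitter keeps the benchmark near zero", {
  cfg <- small_two_choice_cfg(max_rewards = 6L)
  rig <- rig_clocks(
    mcu = clock_spec(jitter_sd_ms = 0.5, period_ms = 1e-6),
    program = clock_spec(jitter_sd_ms = 0.5, period_ms = 1e-6))
  raw <- run_session(cfg, agent_policy(d_true = 3), rig = rig, seed = 9)
  cd <- clock_discrepancy(raw)
  expect_gt(cd$n_epochs, 10)
  expect_lt(cd$mean_ms, 2)
})

test_that("aligned trials respect the anchor sign conventions", {
  s <- shared_aligned_session()
  raw <- shared_raw_session()
  for (i in seq_len(min(6, length(s$trials)))) {
    tr <- s$trials[[i]]
    expect_equal(sum(tr$is_epoch_start), 1)
    # the anchor-onset timestamp is (close to) zero on the MCU clock
    expect_lt(abs(tr$timestamps[tr$is_epoch_start]), 0.005)
    # encoder samples in the approach epoch: negative time, negative
    # distance-to-go; grating samples non-negative position
    enc <- tr$encoder_combined
    pre <- enc[, 1] < -0.02
    expect_true(all(enc[pre, 2] < 0))
    expect_true(all(enc[enc[, 2] >= 0, 1] > -0.02))
    # MCU events recorded before the anchor have negative timestamps
    expect_true(all(diff(tr$frame_combined[, 2]) > 0))
  }
  # no event lost: flagged timestamps match the per-trial MCU log rows
  keep <- raw$mcu_log$event_code %in% c("LICK_L", "LICK_R", "VALVE_L",
                                        "VALVE_R", "VALVE", "MANUAL_OPEN")
  n_flagged <- sum(vapply(s$trials, function(tr)
    sum(tr$is_lick_left, tr$is_lick_right, tr$is_reward_triggered,
        tr$is_manual_open), integer(1)))
  expect_equal(n_flagged, sum(keep))
})

test_that("alignment output satisfies the record invariants across seeds and paradigms", {
  for (seed in 1:3) {
    raw <- run_session(small_two_choice_cfg(max_rewards = 3L),
                       agent_policy(d_true = 1.5, lapse = 0.1,
                                    p_lick_decision = 0.8),
                       seed = seed)
    expect_equal(nrow(validate_session(align_session(raw))), 0)
  }
  for (seed in 4:5) {
    raw <- run_session(small_gonogo_cfg(max_rewards = 4L),
                       agent_policy(d_true = 1, c_true = 0.3), seed = seed)
    expect_equal(nrow(validate_session(align_session(raw))), 0)
  }
  raw <- run_session(task_preset("hf_shaping") |>
                       (\(cfg) { cfg$session_end$max_rewards <- 4L; cfg })(),
                     agent_policy(c_true = -1.5, p_lick_decision = 0.8),
                     seed = 6)
  expect_equal(nrow(validate_session(align_session(raw))), 0)
})

test_that("trials missing their anchor are excluded with a message", {
  raw <- shared_raw_session()
  raw$boundaries <- raw$boundaries[
    !(raw$boundaries$trial == 1 & raw$boundaries$name == "Grating"), ]
  expect_message(s <- align_session(raw), "anchor")
  expect_equal(s$meta$n_excluded, 1L)
  expect_length(s$trials, length(raw$trials) - 1L)
  expect_equal(nrow(validate_session(s)), 0)
})
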