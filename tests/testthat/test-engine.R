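# Helpers driving the engine event by event on the program clock.
tc_state <- function(cfg = task_preset("two_choice"),
                     schedule = c("vertical", "angled", "vertical"),
                     seed = 1L)
  engine_init(cfg, schedule = schedule, seed = seed)

step <- function(st, cfg, kind, time, ...) advance(st, cfg,
                                                  rig_event(kind, time, ...))

has_action <- function(res, kind, ...) {
  want <- list(...)
  any(vapply(res$actions, function(a) {
    if (a$kind != kind) return(FALSE)
    all(vapply(names(want), function(nm) identical(a[[nm]], want[[nm]]),
               logical(1)))
  }, logical(1)))
}

test_that("distance accumulates, floors at zero, and triggers epochs", {
  cfg <- task_preset("two_choice")
  st <- tc_state(cfg)
  res <- step(st, cfg, "distance_delta", 0.1, delta = -5)
  expect_equal(res$state$dist, 0) # backward motion floors at 0
  res <- step(res$state, cfg, "distance_delta", 0.2, delta = 49.9)
  expect_false(has_action(res, "enter_epoch"))
  res <- step(res$state, cfg, "distance_delta", 0.3, delta = 0.2)
  expect_true(has_action(res, "enter_epoch", name = "Grating"))
  expect_equal(res$state$dist, 0.1, tolerance = 1e-9)
  expect_error(step(res$state, cfg, "distance_delta", 0.1, delta = 1),
               "precedes")
})

test_that("reward-zone licks reward the correct port only", {
  cfg <- task_preset("two_choice")
  st <- tc_state(cfg) # trial 1 is vertical: left is correct
  st <- step(st, cfg, "distance_delta", 1, delta = 50)$state # -> Grating
  res <- step(st, cfg, "distance_delta", 2, delta = 5)
  expect_false(has_action(res, "log", code = "STATE", arg = "RewardZone"))
  # zone not open at 5 cm: a correct-side lick does not open the valve
  res <- step(res$state, cfg, "lick_left", 2.1)
  expect_false(has_action(res, "open_valve"))
  # at 10 cm the zone is open (8.33 cm); wrong side never rewards
  res <- step(res$state, cfg, "distance_delta", 3, delta = 5)
  expect_true(has_action(res, "log", code = "STATE", arg = "RewardZone"))
  res <- step(res$state, cfg, "lick_right", 3.1)
  expect_false(has_action(res, "open_valve"))
  # correct side rewards one drop; a second lick does not
  res <- step(res$state, cfg, "lick_left", 3.2)
  expect_true(has_action(res, "open_valve", side = "left", drops = 1L))
  res <- step(res$state, cfg, "lick_left", 3.3)
  expect_false(has_action(res, "open_valve"))
  expect_equal(res$state$rewards_n, 1L)
})

test_that("x_left boosting delivers three drops from the left port", {
  cfg <- task_preset("two_choice")
  cfg$adjustable$x_left <- TRUE
  st <- tc_state(cfg)
  st <- step(st, cfg, "distance_delta", 1, delta = 60)$state
  res <- step(st, cfg, "lick_left", 1.1)
  expect_true(has_action(res, "open_valve", side = "left", drops = 3L))
  expect_equal(res$state$volume_ul, 18)
})

test_that("automatic delivery fires once, from the stimulus port, when unrewarded", {
  cfg <- task_preset("two_choice")
  cfg$adjustable$auto_water <- TRUE
  st <- tc_state(cfg)
  st <- step(st, cfg, "distance_delta", 1, delta = 50)$state
  st <- step(st, cfg, "distance_delta", 2, delta = 41)$state
  expect_null(auto_delivery_check(st, cfg)) # 41 < 41.67
  res <- step(st, cfg, "distance_delta", 3, delta = 1)
  expect_true(has_action(res, "open_valve", side = "left", auto = TRUE))
  # once per trial
  res2 <- step(res$state, cfg, "distance_delta", 4, delta = 1)
  expect_false(has_action(res2, "open_valve"))

  # an earlier rewarded lick suppresses the auto delivery
  st <- tc_state(cfg)
  st <- step(st, cfg, "distance_delta", 1, delta = 62)$state # 12 cm in
  st <- step(st, cfg, "lick_left", 1.1)$state
  res <- step(st, cfg, "distance_delta", 2, delta = 31)
  expect_false(has_action(res, "open_valve"))

  # disabled option never fires
  cfg$adjustable$auto_water <- FALSE
  st <- tc_state(cfg)
  st <- step(st, cfg, "distance_delta", 1, delta = 95)$state
  expect_null(auto_delivery_check(st, cfg))
})

test_that("go/no-go licks reward only after the response delay", {
  cfg <- task_preset("gonogo")
  st <- engine_init(cfg, schedule = c("go", "nogo"), seed = 1)
  st <- step(st, cfg, "init_touch", 1)$state # decision epoch begins
  res <- step(st, cfg, "lick_left", 1.3) # 0.3 s < 0.5 s delay
  expect_false(has_action(res, "open_valve"))
  res <- step(res$state, cfg, "lick_left", 1.6) # 0.6 s
  expect_true(has_action(res, "open_valve", side = "center"))
  # the early lick still scores the trial as a hit
  st2 <- engine_init(cfg, schedule = c("go", "nogo"), seed = 1)
  st2 <- step(st2, cfg, "init_touch", 1)$state
  st2 <- step(st2, cfg, "lick_left", 1.3)$state
  st2 <- step(st2, cfg, "timer_tick", 5.01, dt = 0.02)$state
  expect_equal(score_trial(st2$trials[[1]], cfg), "hit")
  # no-go trials never reward
  st3 <- engine_init(cfg, schedule = c("nogo"), seed = 1)
  st3 <- step(st3, cfg, "init_touch", 1)$state
  res3 <- step(st3, cfg, "lick_left", 2)
  expect_false(has_action(res3, "open_valve"))
})

test_that("the side-bias deterrent locks within 3-8 same-side trials", {
  det0 <- list(count = 0L, side = NA_character_, locked = NA_character_,
               pending_auto_side = NA_character_,
               thresholds = sample(3:8, 20, replace = TRUE))
  det <- det0
  for (k in 1:8) det <- side_bias_deterrent(det, "left", k)
  expect_identical(det$locked, "left") # threshold is at most 8
  expect_identical(det$pending_auto_side, "right")

  det <- det0
  for (k in 1:2) det <- side_bias_deterrent(det, "left", k)
  expect_true(is.na(det$locked)) # threshold is at least 3

  # a subject-triggered reward from the other side lifts the lock
  det <- det0
  for (k in 1:8) det <- side_bias_deterrent(det, "left", k)
  det <- side_bias_deterrent(det, "right", 9, subject_other = TRUE)
  expect_true(is.na(det$locked))
})

test_that("the deterrent blocks the locked port in the shaping task", {
  cfg <- task_preset("hf_shaping")
  st <- engine_init(cfg, schedule = rep("black", 30), seed = 2)
  st$deterrent$locked <- "left"
  st <- step(st, cfg, "distance_delta", 1, delta = 21)$state # -> Stimulus
  res <- step(st, cfg, "lick_left", 1.5)
  expect_false(has_action(res, "open_valve"))
  res <- step(res$state, cfg, "lick_right", 2)
  expect_true(has_action(res, "open_valve", side = "right"))
})

test_that("parameter updates land at the trial boundary; manual open is immediate", {
  cfg <- task_preset("two_choice")
  st <- tc_state(cfg, schedule = rep("vertical", 5))
  st <- step(st, cfg, "param_update", 0.5, name = "auto_water",
             value = TRUE)$state
  st <- step(st, cfg, "param_update", 0.6, name = "auto_water",
             value = FALSE)$state
  st <- step(st, cfg, "param_update", 0.7, name = "x_right",
             value = TRUE)$state
  expect_false(st$adjustable$auto_water)
  expect_false(st$adjustable$x_right)

  res <- step(st, cfg, "manual_open", 0.8) # approach epoch: random side
  expect_true(has_action(res, "open_valve", manual = TRUE))
  st <- res$state
  expect_equal(st$rewards_n, 1L)

  st <- step(st, cfg, "distance_delta", 1, delta = 100)$state # trial ends
  # last write wins; both queued updates applied at the boundary
  expect_false(st$adjustable$auto_water)
  expect_true(st$adjustable$x_right)
  expect_equal(length(st$param_log), 2L)
})

test_that("session-end rules fire on rewards or duration, whichever first", {
  cfg <- task_preset("two_choice")
  st <- tc_state(cfg)
  st$rewards_n <- 125L; st$t <- 40 * 60
  expect_equal(session_end_check(st, cfg)$reason, "max_rewards")
  st$rewards_n <- 10L; st$t <- 90 * 60
  expect_equal(session_end_check(st, cfg)$reason, "max_duration")
  st$rewards_n <- 124L; st$t <- 89.9 * 60
  expect_null(session_end_check(st, cfg))
})

test_that("trial scoring uses the first in-zone lick", {
  cfg <- task_preset("two_choice")
  trial <- function(type, sides, dists)
    list(type = type,
         licks = list(side = sides, dist = dists,
                      epoch = rep("Grating", length(sides)),
                      time = seq_along(sides),
                      t_in_epoch = seq_along(sides)))
  expect_equal(score_trial(trial("vertical", "left", 20), cfg),
               "hit_vertical")
  expect_equal(score_trial(trial("angled", "left", 20), cfg), "fa_angled")
  expect_equal(score_trial(trial("angled", c("right", "left"), c(20, 30)),
                           cfg), "hit_angled")
  # out-of-zone licks do not count
  expect_equal(score_trial(trial("vertical", "left", 5), cfg),
               "no_interaction")
  expect_equal(score_trial(trial("vertical", character(0), numeric(0)),
                           cfg), "no_interaction")
})

test_that("rewards are conserved and never from the incorrect port", {
  raw <- shared_raw_session()
  expect_equal(raw$rewards_n * raw$config$reward_volume_ul, raw$volume_ul)
  # exhaustive check over the simulated session: left valve only on
  # vertical trials, right valve only on angled trials
  types <- vapply(raw$trials, `[[`, character(1), "type")
  v <- raw$mcu_log[raw$mcu_log$event_code %in% c("VALVE_L", "VALVE_R"), ]
  expect_true(all(types[v$trial[v$event_code == "VALVE_L"]] == "vertical"))
  expect_true(all(types[v$trial[v$event_code == "VALVE_R"]] == "angled"))
})

test_that("the engine is deterministic given config, schedule and events", {
  cfg <- task_preset("two_choice")
  run_once <- function() {
    st <- tc_state(cfg, schedule = c("vertical", "angled"), seed = 9)
    st <- step(st, cfg, "distance_delta", 1, delta = 55)$state
    st <- step(st, cfg, "lick_left", 1.5)$state
    st <- step(st, cfg, "distance_delta", 2, delta = 50)$state
    st
  }
  expect_equal(run_once(), run_once())
})
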