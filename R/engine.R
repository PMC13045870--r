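# Event-driven finite-state task engine. The engine is a pure transition
# function: advance(state, config, event) returns the next state plus the
# actions the rig must execute (valve openings, epoch entries, log lines).
# All within-session randomness (deterrent thresholds, random-side
# releases) is derived deterministically from the session seed, so the
# engine is fully determined by (config, schedule, event sequence, seed).

#' Construct a rig event
#'
#' @param kind One of `lick_left`, `lick_right`, `init_touch`,
#'   `distance_delta`, `timer_tick`, `manual_open`, `param_update`.
#' @param time Event time on the program clock, in s from session onset.
#' @param delta Distance increment in cm (`distance_delta`; may be
#'   negative for backward wheel motion).
#' @param dt Tick duration in s (`timer_tick`).
#' @param side Valve side for `manual_open` outside a decision epoch.
#' @param name,value Parameter name and new value (`param_update`).
#' @return A list usable as the `event` argument of [advance()].
#' @export
rig_event <- function(kind, time, delta = NULL, dt = NULL, side = NULL,
                      name = NULL, value = NULL) {
  list(kind = kind, time = time, delta = delta, dt = dt, side = side,
       name = name, value = value)
}

#' Initialize the task engine
#'
#' Builds the engine state for a session: the full trial-type schedule is
#' generated up front (so the parameter-change log can reference a fixed
#' schedule), trial 1 begins in the first epoch at time 0.
#'
#' @param config A [task_config()].
#' @param schedule Optional pre-generated schedule (character vector);
#'   generated from `config$schedule` when omitted.
#' @param seed Session seed; engine-internal draws (deterrent thresholds,
#'   random-side releases) come from sub-streams of it.
#' @return An object of class `engine_state`.
#' @export
engine_init <- function(config, schedule = NULL, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  if (is.null(schedule)) schedule <- generate_schedule(config$schedule)
  det_thr <- with_seed(derive_seed(seed, "deterrent"),
                       sample(3:8, length(schedule), replace = TRUE))
  structure(list(
    schedule = schedule, seed = as.integer(seed),
    trial_idx = 1L, epoch_idx = 1L,
    epoch_name = config$epochs[[1]]$name,
    dist = 0, t = 0, epoch_t0 = 0, trial_t0 = 0,
    in_iti = FALSE, iti_t0 = NA_real_,
    zone_entered = FALSE, rewarded = FALSE, rewarded_side = NA_character_,
    auto_done = FALSE, reward_time = NA_real_,
    rewards_n = 0L, volume_ul = 0,
    cur_licks = list(side = character(0), time = numeric(0),
                     dist = numeric(0), epoch = character(0),
                     t_in_epoch = numeric(0)),
    trials = list(),
    adjustable = config$adjustable,
    pending_updates = list(),
    param_log = list(),
    deterrent = list(count = 0L, side = NA_character_,
                     locked = NA_character_,
                     pending_auto_side = NA_character_,
                     thresholds = det_thr),
    session_ended = FALSE, end_reason = NA_character_,
    started = TRUE),
    class = "engine_state")
}

#' @export
print.engine_state <- function(x, ...) {
  cat(sprintf(
    "Engine state: trial %d (%s), epoch %s, dist %.2f cm, t %.2f s, %d rewards\n",
    x$trial_idx, x$schedule[min(x$trial_idx, length(x$schedule))],
    if (x$in_iti) "ITI" else x$epoch_name, x$dist, x$t, x$rewards_n))
  invisible(x)
}

trial_type_now <- function(state) state$schedule[state$trial_idx]

contingent_port <- function(config, trial_type) {
  row <- config$contingency[config$contingency$trial_type == trial_type, ]
  if (nrow(row) == 0L) return(NA_character_)
  row$reward_port[1]
}

act_valve <- function(side, drops = 1L, auto = FALSE, manual = FALSE)
  list(kind = "open_valve", side = side, drops = drops, auto = auto,
       manual = manual)
act_epoch <- function(name) list(kind = "enter_epoch", name = name)
act_log <- function(code, arg = "") list(kind = "log", code = code,
                                         arg = arg)
act_end_trial <- function() list(kind = "end_trial")
act_end_session <- function(reason) list(kind = "end_session",
                                         reason = reason)

# deterministic "random" side for random-port releases
random_side <- function(state) {
  u <- with_seed(derive_seed(state$seed,
                             paste0("side", state$trial_idx)), runif(1))
  if (u < 0.5) "left" else "right"
}

dispense <- function(state, config, side, drops = 1L, auto = FALSE,
                     manual = FALSE) {
  state$rewards_n <- state$rewards_n + as.integer(drops)
  state$volume_ul <- state$volume_ul + drops * config$reward_volume_ul
  if (!auto && !manual) {
    state$rewarded <- TRUE
    state$rewarded_side <- side
    state$reward_time <- state$t
  }
  if (auto) state$auto_done <- TRUE
  list(state = state, action = act_valve(side, drops, auto, manual))
}

drops_for_side <- function(state, side) {
  if (side == "left" && isTRUE(state$adjustable$x_left)) return(3L)
  if (side == "right" && isTRUE(state$adjustable$x_right)) return(3L)
  1L
}

#' Check whether the automatic reward delivery should fire
#'
#' In the closed-loop task, when automatic water delivery is enabled a
#' reward is delivered from the lick-port associated with the presented
#' stimulus at the first distance sample at or beyond the auto-delivery
#' distance (~41.67 cm into the grating epoch), but only once per trial
#' and only when no correct rewarded lick occurred earlier in the trial.
#'
#' @param state An `engine_state` currently in the decision epoch.
#' @param config The [task_config()].
#' @return An `open_valve` action, or `NULL` when the conditions are not
#'   met.
#' @export
auto_delivery_check <- function(state, config) {
  if (!isTRUE(state$adjustable$auto_water)) return(NULL)
  if (state$auto_done || state$rewarded) return(NULL)
  if (is.null(config$reward_zone) ||
      state$dist < config$reward_zone[["close"]]) return(NULL)
  side <- contingent_port(config, trial_type_now(state))
  act_valve(side, 1L, auto = TRUE)
}

#' Update the side-bias deterrent after a trial
#'
#' Shaping-task rule: count consecutive trials whose rewarded lick was on
#' the same side; the criterion threshold is redrawn uniformly from
#' 3..8 every trial. On reaching the threshold that side is locked (no
#' further water from it) and an automatic release from the other side is
#' scheduled for 2 s after the next stimulus change; the lock is lifted
#' only after a trial in which the subject itself triggered the other
#' side.
#'
#' @param det The deterrent sub-state
#'   (`list(count, side, locked, pending_auto_side, thresholds)`).
#' @param rewarded_side Side of this trial's subject-triggered reward
#'   (`"left"`, `"right"`, or `NA` when none).
#' @param trial Trial index (selects the pre-drawn threshold).
#' @param subject_other `TRUE` when, under a lock, the subject triggered
#'   the non-locked side this trial (lifts the lock).
#' @return The updated deterrent sub-state; `$locked` carries the lock
#'   decision.
#' @export
side_bias_deterrent <- function(det, rewarded_side, trial,
                                subject_other = FALSE) {
  if (!is.na(det$locked) && subject_other) {
    det$locked <- NA_character_
    det$pending_auto_side <- NA_character_
    det$count <- 0L
    det$side <- NA_character_
  }
  if (is.na(rewarded_side)) return(det)
  if (!is.na(det$side) && det$side == rewarded_side)
    det$count <- det$count + 1L
  else { det$side <- rewarded_side; det$count <- 1L }
  thr <- det$thresholds[min(trial, length(det$thresholds))]
  if (is.na(det$locked) && det$count >= thr) {
    det$locked <- rewarded_side
    det$pending_auto_side <- setdiff(c("left", "right"), rewarded_side)
  }
  det
}

#' Queue a within-session parameter update
#'
#' Updates queue during a trial and take effect at the next trial
#' boundary (the GUI accepts callbacks at the end of each trial); manual
#' valve commands are a separate immediate event ([rig_event()] kind
#' `manual_open`). Two queued updates to the same parameter: last write
#' wins.
#'
#' @param state An `engine_state`.
#' @param name Adjustable parameter name (e.g. `"auto_water"`, `"x_left"`).
#' @param value New value.
#' @return The updated state.
#' @export
apply_parameter_update <- function(state, name, value) {
  state$pending_updates[[name]] <- value
  state
}

#' Check the session-end rules
#'
#' The session ends once the reward count reaches `max_rewards` or the
#' elapsed time reaches `max_duration_min`, whichever comes first.
#'
#' @param state An `engine_state`.
#' @param config The [task_config()].
#' @return An `end_session` action (with `$reason`), or `NULL`.
#' @export
session_end_check <- function(state, config) {
  if (state$rewards_n >= config$session_end$max_rewards)
    return(act_end_session("max_rewards"))
  if (state$t - 0 >= config$session_end$max_duration_min * 60)
    return(act_end_session("max_duration"))
  NULL
}

close_trial <- function(state, config) {
  tt <- trial_type_now(state)
  state$trials[[length(state$trials) + 1L]] <- list(
    trial_idx = state$trial_idx, type = tt, licks = state$cur_licks,
    rewarded = state$rewarded, rewarded_side = state$rewarded_side,
    trial_t0 = state$trial_t0, t_end = state$t)
  # deterrent bookkeeping (shaping): consecutive same-side rewarded trials
  if (isTRUE(state$adjustable$side_bias_rule)) {
    subject_other <- !is.na(state$deterrent$locked) && state$rewarded &&
      !is.na(state$rewarded_side) &&
      state$rewarded_side != state$deterrent$locked
    state$deterrent <- side_bias_deterrent(
      state$deterrent,
      if (state$rewarded) state$rewarded_side else NA_character_,
      state$trial_idx, subject_other = subject_other)
  }
  # parameter updates land at the trial boundary
  if (length(state$pending_updates)) {
    for (nm in names(state$pending_updates))
      state$param_log[[length(state$param_log) + 1L]] <- list(
        trial = state$trial_idx, parameter = nm,
        old = state$adjustable[[nm]] %||% NA,
        new = state$pending_updates[[nm]])
    state$adjustable <- utils::modifyList(state$adjustable,
                                          state$pending_updates)
    state$pending_updates <- list()
  }
  state
}

begin_trial <- function(state, config) {
  state$trial_idx <- state$trial_idx + 1L
  state$epoch_idx <- 1L
  state$epoch_name <- config$epochs[[1]]$name
  state$dist <- 0
  state$epoch_t0 <- state$t
  state$trial_t0 <- state$t
  state$in_iti <- FALSE
  state$zone_entered <- FALSE
  state$rewarded <- FALSE
  state$rewarded_side <- NA_character_
  state$auto_done <- FALSE
  state$reward_time <- NA_real_
  state$cur_licks <- list(side = character(0), time = numeric(0),
                          dist = numeric(0), epoch = character(0),
                          t_in_epoch = numeric(0))
  state
}

enter_next_epoch <- function(state, config) {
  state$epoch_idx <- state$epoch_idx + 1L
  state$epoch_name <- config$epochs[[state$epoch_idx]]$name
  state$epoch_t0 <- state$t
  state
}

end_trial_actions <- function(state, config) {
  acts <- list(act_log("STATE", paste0(state$epoch_name, "End")),
               act_end_trial())
  state <- close_trial(state, config)
  endchk <- session_end_check(state, config)
  if (!is.null(endchk)) {
    state$session_ended <- TRUE
    state$end_reason <- endchk$reason
    acts[[length(acts) + 1L]] <- endchk
  } else if (state$trial_idx >= length(state$schedule)) {
    state$session_ended <- TRUE
    state$end_reason <- "manual"
    acts[[length(acts) + 1L]] <- act_end_session("manual")
  } else {
    state$in_iti <- TRUE
    state$iti_t0 <- state$t
  }
  list(state = state, actions = acts)
}

maybe_end_session_on_reward <- function(state, config, acts) {
  if (state$rewards_n >= config$session_end$max_rewards &&
      !state$session_ended) {
    state <- close_trial(state, config)
    state$session_ended <- TRUE
    state$end_reason <- "max_rewards"
    acts[[length(acts) + 1L]] <- act_end_session("max_rewards")
  }
  list(state = state, actions = acts)
}

record_lick <- function(state, side) {
  L <- state$cur_licks
  L$side <- c(L$side, side)
  L$time <- c(L$time, state$t)
  L$dist <- c(L$dist, state$dist)
  L$epoch <- c(L$epoch, if (state$in_iti) "ITI" else state$epoch_name)
  L$t_in_epoch <- c(L$t_in_epoch, state$t - state$epoch_t0)
  state$cur_licks <- L
  state
}

#' Advance the task engine by one event
#'
#' The pure transition function of the engine. Distance-triggered epoch
#' transitions fire when the accumulated distance reaches the epoch
#' length (backward wheel motion decrements distance but floors at 0);
#' in the decision epoch of the two-choice task the first lick at the
#' correct port with distance at or beyond the reward-zone opening and
#' before the auto-delivery distance triggers a reward (one drop, or
#' three when the side's boost flag is set); in Go/No-go a lick at least
#' `response_delay` after decision-epoch onset on a Go trial triggers one
#' reward. Incorrect-side licks never open a valve.
#'
#' @param state An `engine_state` from [engine_init()].
#' @param config The [task_config()].
#' @param event A [rig_event()].
#' @return `list(state =, actions =)` where `actions` is a (possibly
#'   empty) list of valve/epoch/log/trial/session actions.
#' @export
advance <- function(state, config, event) {
  if (!isTRUE(state$started)) stop_fmt("event before session start")
  if (state$session_ended) return(list(state = state, actions = list()))
  if (event$time < state$t - 1e-9)
    stop_fmt("event time %.4f precedes engine clock %.4f", event$time,
             state$t)
  state$t <- event$time
  kind <- event$kind
  acts <- list()

  if (kind == "param_update")
    return(list(state = apply_parameter_update(state, event$name,
                                               event$value),
                actions = list()))

  if (kind == "manual_open") {
    dec <- state$epoch_name == config$epochs[[length(config$epochs)]]$name
    side <- if (dec && !state$in_iti &&
                config$task_kind == "two_choice_closed_loop")
      contingent_port(config, trial_type_now(state))
    else event$side %||% random_side(state)
    d <- dispense(state, config, side, 1L, manual = TRUE)
    state <- d$state
    acts <- list(act_log("MANUAL_OPEN", side), d$action)
    res <- maybe_end_session_on_reward(state, config, acts)
    return(list(state = res$state, actions = res$actions))
  }

  if (state$in_iti) {
    if (kind %in% c("lick_left", "lick_right"))
      state <- record_lick(state, sub("lick_", "", kind))
    if (kind %in% c("timer_tick", "distance_delta") &&
        state$t - state$iti_t0 >= config$iti - 1e-9) {
      state <- begin_trial(state, config)
      acts <- list(act_log("STATE", state$epoch_name),
                   act_epoch(state$epoch_name))
      endchk <- session_end_check(state, config)
      if (!is.null(endchk)) {
        state$session_ended <- TRUE
        state$end_reason <- endchk$reason
        acts[[length(acts) + 1L]] <- endchk
      }
    }
    return(list(state = state, actions = acts))
  }

  epoch <- config$epochs[[state$epoch_idx]]
  decision <- state$epoch_idx == length(config$epochs)

  if (kind == "distance_delta") {
    state$dist <- max(0, state$dist + event$delta)
    if (epoch$trigger == "distance" && !decision &&
        state$dist >= epoch$value) {
      carry <- state$dist - epoch$value
      state <- enter_next_epoch(state, config)
      state$dist <- carry
      acts[[length(acts) + 1L]] <- act_log("STATE", state$epoch_name)
      acts[[length(acts) + 1L]] <- act_epoch(state$epoch_name)
      epoch <- config$epochs[[state$epoch_idx]]
      decision <- TRUE
    }
    if (decision && epoch$trigger == "distance") {
      if (!state$zone_entered && !is.null(config$reward_zone) &&
          state$dist >= config$reward_zone[["open"]]) {
        state$zone_entered <- TRUE
        acts[[length(acts) + 1L]] <- act_log("STATE", "RewardZone")
      }
      auto <- auto_delivery_check(state, config)
      if (!is.null(auto)) {
        d <- dispense(state, config, auto$side, auto$drops, auto = TRUE)
        state <- d$state
        acts[[length(acts) + 1L]] <- d$action
        res <- maybe_end_session_on_reward(state, config, acts)
        state <- res$state; acts <- res$actions
        if (state$session_ended)
          return(list(state = state, actions = acts))
      }
      if (state$dist >= epoch$value) {
        res <- end_trial_actions(state, config)
        return(list(state = res$state,
                    actions = c(acts, res$actions)))
      }
    }
    return(list(state = state, actions = acts))
  }

  if (kind == "timer_tick") {
    if (epoch$trigger == "timer") {
      el <- state$t - state$epoch_t0
      # shaping auto release (manual auto-water option, or the deterrent
      # rule's scheduled release from the non-locked side)
      if (decision && !state$rewarded && !state$auto_done &&
          (isTRUE(state$adjustable$auto_water) ||
             !is.na(state$deterrent$pending_auto_side)) &&
          el >= config$auto_release_delay &&
          config$task_kind %in% c("hf_shaping", "fm_shaping_1",
                                  "fm_shaping_2")) {
        side <- state$deterrent$pending_auto_side
        if (is.na(side))
          side <- if (config$task_kind == "hf_shaping")
            random_side(state) else "center"
        d <- dispense(state, config, side, 1L, auto = TRUE)
        state <- d$state
        acts[[length(acts) + 1L]] <- d$action
        if (!is.na(state$deterrent$pending_auto_side))
          state$deterrent$pending_auto_side <- NA_character_
        res <- maybe_end_session_on_reward(state, config, acts)
        state <- res$state; acts <- res$actions
        if (state$session_ended)
          return(list(state = state, actions = acts))
      }
      done <- el >= epoch$value - 1e-9
      # lick-terminated stimulus epochs end 0.5 s after the reward
      if (decision && config$task_kind %in% c("fm_shaping_1",
                                              "fm_shaping_2") &&
          state$rewarded && state$t - state$reward_time >= 0.5 - 1e-9)
        done <- TRUE
      if (done) {
        if (decision) {
          res <- end_trial_actions(state, config)
          return(list(state = res$state, actions = c(acts, res$actions)))
        }
        state <- enter_next_epoch(state, config)
        acts[[length(acts) + 1L]] <- act_log("STATE", state$epoch_name)
        acts[[length(acts) + 1L]] <- act_epoch(state$epoch_name)
      }
    }
    return(list(state = state, actions = acts))
  }

  if (kind == "init_touch") {
    acts[[length(acts) + 1L]] <- act_log("INIT_TOUCH")
    if (epoch$trigger == "event" && epoch$value == "init_touch") {
      state <- enter_next_epoch(state, config)
      acts[[length(acts) + 1L]] <- act_log("STATE", state$epoch_name)
      acts[[length(acts) + 1L]] <- act_epoch(state$epoch_name)
    }
    return(list(state = state, actions = acts))
  }

  if (kind %in% c("lick_left", "lick_right")) {
    side <- sub("lick_", "", kind)
    state <- record_lick(state, side)
    if (!decision)
      return(list(state = state, actions = acts))
    tt <- trial_type_now(state)
    open_ok <- FALSE
    drops <- 1L
    vside <- side
    if (config$task_kind == "two_choice_closed_loop") {
      cs <- config$contingency$correct_side[
        config$contingency$trial_type == tt]
      open_ok <- state$zone_entered && !state$rewarded &&
        state$dist < config$reward_zone[["close"]] && side == cs
      drops <- drops_for_side(state, side)
    } else if (config$task_kind == "hf_shaping") {
      locked <- state$deterrent$locked
      open_ok <- !state$rewarded && (is.na(locked) || side != locked)
      drops <- 1L
    } else if (config$task_kind == "gonogo_freely_moving") {
      open_ok <- tt == "go" && !state$rewarded &&
        (state$t - state$epoch_t0) >= config$response_delay - 1e-9
      vside <- "center"
    } else { # fm shaping stages: any lick during the stimulus rewards
      open_ok <- !state$rewarded &&
        (state$t - state$epoch_t0) >= config$response_delay - 1e-9
      vside <- "center"
    }
    if (open_ok) {
      d <- dispense(state, config, vside, drops)
      state <- d$state
      acts[[length(acts) + 1L]] <- d$action
      res <- maybe_end_session_on_reward(state, config, acts)
      state <- res$state; acts <- res$actions
    }
    return(list(state = state, actions = acts))
  }

  stop_fmt("unknown event kind '%s'", kind)
}

#' Score a completed trial
#'
#' Two-choice scoring: the decision is the side of the first lick whose
#' corridor distance lies within the reward zone of the grating epoch;
#' `hit_vertical` / `fa_angled` are left licks on vertical / angled
#' trials, `hit_angled` / `fa_vertical` right licks; trials without an
#' in-zone lick are `no_interaction`. Go/No-go: any lick during the
#' decision epoch makes a Go trial a `hit` and a No-go trial a
#' `false_alarm`; otherwise `miss` / `correct_reject`. Licks during the
#' Go/No-go response delay count for scoring even though they cannot
#' trigger reward.
#'
#' @param trial One element of `engine_state$trials` (as recorded by
#'   [advance()]), or a list with `type` and `licks`.
#' @param config The [task_config()].
#' @return A single outcome label.
#' @export
score_trial <- function(trial, config) {
  licks <- trial$licks
  if (config$task_kind == "two_choice_closed_loop") {
    dec_name <- config$epochs[[length(config$epochs)]]$name
    zone <- config$reward_zone
    in_zone <- licks$epoch == dec_name & licks$dist >= zone[["open"]] &
      licks$dist < zone[["close"]]
    if (!any(in_zone)) return("no_interaction")
    first <- licks$side[which(in_zone)[1]]
    if (trial$type == "vertical")
      return(if (first == "left") "hit_vertical" else "fa_vertical")
    return(if (first == "left") "fa_angled" else "hit_angled")
  }
  if (config$task_kind == "gonogo_freely_moving") {
    dec_name <- config$epochs[[length(config$epochs)]]$name
    licked <- any(licks$epoch == dec_name)
    if (trial$type == "go") return(if (licked) "hit" else "miss")
    return(if (licked) "false_alarm" else "correct_reject")
  }
  # shaping tasks: rewarded / unrewarded
  if (isTRUE(trial$rewarded)) "hit" else "miss"
}
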