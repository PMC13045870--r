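# Synthetic-data generator: simulated device clocks, multi-rate sensor
# streams, eye frames, and a signal-detection virtual mouse. Every module
# downstream of hardware is testable against the ground truth this rig
# records alongside the raw streams.

#' Specify a simulated device clock
#'
#' A device clock maps true time to device time as
#' `t_dev = (t_true + offset) * (1 + drift * 1e-6) + N(0, jitter_sd)`,
#' then quantizes down to the clock's sampling-period grid.
#'
#' @param offset Clock offset in s.
#' @param drift_ppm Clock drift in parts per million.
#' @param jitter_sd_ms Timestamping jitter SD in ms.
#' @param period_ms Sampling period in ms (> 0); the MCU polls at 300 Hz
#'   (period 10/3 ms).
#' @return An object of class `clock_spec`.
#' @export
clock_spec <- function(offset = 0, drift_ppm = 0, jitter_sd_ms = 0,
                       period_ms = 1000 / 300) {
  stopifnot(period_ms > 0, jitter_sd_ms >= 0)
  structure(list(offset = offset, drift_ppm = drift_ppm,
                 jitter_sd_ms = jitter_sd_ms, period_ms = period_ms),
            class = "clock_spec")
}

#' Default simulated rig clock set
#'
#' The platform uses two clocks: the lick-port controller's (MCU #1,
#' 300 Hz polling) and the computer program's (high-resolution, the
#' reference for external-device streams).
#'
#' @param mcu,program [clock_spec()]s for the two clocks.
#' @return Named list of clock specs.
#' @export
rig_clocks <- function(mcu = clock_spec(offset = 0.005, drift_ppm = 10,
                                        jitter_sd_ms = 0.2,
                                        period_ms = 1000 / 300),
                       program = clock_spec(offset = 0, drift_ppm = 0,
                                            jitter_sd_ms = 0.05,
                                            period_ms = 0.01)) {
  list(mcu = mcu, program = program)
}

#' Read a device clock
#'
#' @param clock A [clock_spec()].
#' @param t_true True time(s) in s.
#' @return Device time(s) in s (vectorized). Jitter draws use the current
#'   RNG stream.
#' @export
clock_read <- function(clock, t_true) {
  t <- (t_true + clock$offset) * (1 + clock$drift_ppm * 1e-6)
  if (clock$jitter_sd_ms > 0)
    t <- t + rnorm(length(t), 0, clock$jitter_sd_ms / 1000)
  p <- clock$period_ms / 1000
  # epsilon guards on-grid times against floating-point floor slips
  floor(t / p + 1e-9) * p
}

#' Specify the virtual mouse
#'
#' An equal-variance signal-detection agent: on each engaged decision the
#' internal evidence is drawn from `Normal(+d_true/2, 1)` for the
#' left-rewarded stimulus class and `Normal(-d_true/2, 1)` for the
#' right-rewarded class, and the agent responds left when evidence
#' exceeds `c_true`. Positive `c_true` therefore biases responses to the
#' right (the left-lick-positive convention), and the analysis module's
#' d-prime and side-bias index estimates have known targets `d_true` and
#' `c_true`.
#'
#' @param d_true Sensitivity in z-units.
#' @param c_true Criterion in z-units (positive = right bias).
#' @param lapse Lapse probability: respond with a uniform random side.
#' @param p_lick_approach Per-trial probability of a (non-scoring) lick
#'   during the approach epoch.
#' @param p_lick_decision Per-trial engagement probability; with
#'   probability `1 - p_lick_decision` the agent makes no response.
#' @param lick_rate Within-bout lick rate in Hz.
#' @param speed_mean,speed_sd Locomotion speed process (truncated normal,
#'   floor 0) in cm/s, sampled per 300 Hz tick.
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(d_true = 2, c_true = 0, lapse = 0,
                         p_lick_approach = 0.1, p_lick_decision = 1,
                         lick_rate = 6, speed_mean = 15, speed_sd = 5) {
  stopifnot(lapse >= 0, lapse <= 1, p_lick_approach >= 0,
            p_lick_approach <= 1, p_lick_decision >= 0,
            p_lick_decision <= 1, lick_rate >= 0, speed_mean > 0)
  structure(list(d_true = d_true, c_true = c_true, lapse = lapse,
                 p_lick_approach = p_lick_approach,
                 p_lick_decision = p_lick_decision,
                 lick_rate = lick_rate, speed_mean = speed_mean,
                 speed_sd = speed_sd), class = "agent_policy")
}

#' Draw one response from the virtual mouse
#'
#' Uses the current RNG stream; seed it (or wrap in a seeded stream) for
#' reproducibility.
#'
#' @param policy An [agent_policy()].
#' @param trial_type Trial label. For `paradigm = "two_choice"`,
#'   `"vertical"` is the left-rewarded class; anything else is
#'   right-rewarded. For `paradigm = "gonogo"`, `"go"` is the
#'   respond class.
#' @param paradigm `"two_choice"` or `"gonogo"`.
#' @return `"left"`, `"right"`, or `"none"` (two-choice); `"lick"` or
#'   `"none"` (Go/No-go).
#' @export
sample_choice <- function(policy, trial_type,
                          paradigm = c("two_choice", "gonogo")) {
  paradigm <- match.arg(paradigm)
  if (runif(1) > policy$p_lick_decision) return("none")
  positive <- trial_type %in% c("vertical", "go")
  if (runif(1) < policy$lapse) {
    if (paradigm == "gonogo") return(if (runif(1) < 0.5) "lick" else "none")
    return(if (runif(1) < 0.5) "left" else "right")
  }
  evidence <- rnorm(1, mean = if (positive) policy$d_true / 2
                              else -policy$d_true / 2)
  if (paradigm == "gonogo")
    return(if (evidence > policy$c_true) "lick" else "none")
  if (evidence > policy$c_true) "left" else "right"
}

# growable numeric/character buffer (amortized append)
buf_new <- function(mode = "numeric", cap = 4096L) {
  e <- new.env(parent = emptyenv())
  e$x <- vector(mode, cap)
  e$n <- 0L
  e
}
buf_add <- function(e, v) {
  k <- length(v)
  while (e$n + k > length(e$x)) e$x <- c(e$x, vector(typeof(e$x),
                                                     length(e$x)))
  e$x[(e$n + 1L):(e$n + k)] <- v
  e$n <- e$n + k
  invisible(e)
}
buf_get <- function(e) if (e$n == 0L) e$x[0] else e$x[seq_len(e$n)]

truth_outcome <- function(task_kind, type, response) {
  if (task_kind == "two_choice_closed_loop") {
    if (response == "none") return("no_interaction")
    if (type == "vertical")
      return(if (response == "left") "hit_vertical" else "fa_vertical")
    return(if (response == "left") "fa_angled" else "hit_angled")
  }
  if (task_kind == "gonogo_freely_moving") {
    if (type == "go") return(if (response == "lick") "hit" else "miss")
    return(if (response == "lick") "false_alarm" else "correct_reject")
  }
  if (response == "none") "miss" else "hit"
}

#' Simulate a full session end-to-end
#'
#' Runs the task engine against the virtual mouse and simulated device
#' clocks, producing (a) the MCU #1 event log on the MCU clock, (b)
#' encoder samples at 300 Hz and camera frame triggers at 10 Hz on the
#' program clock, and (c) ground-truth annotations (true event times,
#' true outcomes, true pupil radii) sufficient to check every downstream
#' stage independently of the engine. The closed-loop coupling is 1 cm of
#' wheel travel = 1 cm of stimulus corridor.
#'
#' All randomness flows from `seed` via named sub-streams (`schedule`,
#' `agent`, `clocks`, `frames`), so components are independently
#' reproducible.
#'
#' @param config A [task_config()].
#' @param policy An [agent_policy()].
#' @param rig A [rig_clocks()] list.
#' @param seed Integer session seed.
#' @return An object of class `raw_session`: `mcu_log` (data frame on the
#'   MCU clock, with the rig's trial annotation), `encoder` and `frames`
#'   streams on the program clock, `boundaries` (epoch boundary times on
#'   both clocks), `truth` (per-trial type/response/outcome, pupil radii
#'   per frame), engine `trials`, and session metadata.
#' @export
run_session <- function(config, policy = agent_policy(),
                        rig = rig_clocks(), seed = 1L) {
  stopifnot(inherits(config, "task_config"),
            inherits(policy, "agent_policy"))
  sched <- config$schedule
  sched$seed <- derive_seed(seed, "schedule")
  schedule <- generate_schedule(sched)
  state <- engine_init(config, schedule = schedule,
                       seed = derive_seed(seed, "engine"))
  closed_loop <- config$epochs[[1]]$trigger == "distance"
  dt <- if (closed_loop) 1 / 300 else 0.02
  epoch1_len <- if (config$epochs[[1]]$trigger == "distance")
    config$epochs[[1]]$value else 0

  mcu_t <- buf_new(); mcu_code <- buf_new("character")
  mcu_arg <- buf_new("character"); mcu_trial <- buf_new("integer")
  bnd_t <- buf_new(); bnd_name <- buf_new("character")
  bnd_trial <- buf_new("integer"); bnd_row <- buf_new("integer")

  log_mcu <- function(t, code, arg, trial) {
    buf_add(mcu_t, t); buf_add(mcu_code, code); buf_add(mcu_arg, arg)
    buf_add(mcu_trial, trial)
    mcu_t$n
  }
  log_boundary <- function(t, name, trial, row) {
    buf_add(bnd_t, t); buf_add(bnd_name, name); buf_add(bnd_trial, trial)
    buf_add(bnd_row, row)
  }

  truth_rows <- list()
  t <- 0
  set.seed(derive_seed(seed, "agent"))
  plan <- NULL
  planned_trial <- 0L

  plan_trial <- function(type) {
    if (config$task_kind == "two_choice_closed_loop") {
      resp <- sample_choice(policy, type, "two_choice")
      lick_pos <- if (resp == "none") NA_real_ else
        runif(1, config$reward_zone[["open"]],
              config$reward_zone[["close"]] - 1e-6)
      appr <- if (runif(1) < policy$p_lick_approach)
        runif(1, 2, epoch1_len - 2) else NA_real_
      appr_side <- if (runif(1) < 0.5) "left" else "right"
      n_extra <- if (resp == "none" || policy$lick_rate <= 0) 0L
                 else rbinom(1, 3, 0.6)
      list(resp = resp, lick_pos = lick_pos, appr_pos = appr,
           appr_side = appr_side, n_extra = n_extra,
           extra_left = 0L, fired = FALSE, appr_fired = is.na(appr),
           next_extra_t = NA_real_)
    } else if (config$task_kind %in% c("gonogo_freely_moving",
                                       "fm_shaping_1", "fm_shaping_2")) {
      resp <- sample_choice(policy, type, "gonogo")
      lick_t <- if (resp == "none") NA_real_ else
        runif(1, 0.15, max(0.3, config$stimulus_duration - 0.2))
      delay <- runif(1, config$prestim_delay_range[1],
                     config$prestim_delay_range[2])
      list(resp = resp, lick_t = lick_t, init_delay = delay,
           fired = FALSE, init_fired = FALSE)
    } else { # hf_shaping: side preference governed by the criterion
      engaged <- runif(1) < policy$p_lick_decision
      side <- if (runif(1) < pnorm(-policy$c_true)) "left" else "right"
      lick_t <- if (engaged) runif(1, 0.2, config$stimulus_duration - 0.5)
                else NA_real_
      list(resp = if (engaged) side else "none", lick_t = lick_t,
           fired = FALSE)
    }
  }

  do_actions <- function(actions, t) {
    for (a in actions) {
      if (a$kind == "open_valve") {
        code <- if (a$manual) "MANUAL_OPEN"
                else switch(a$side, left = "VALVE_L", right = "VALVE_R",
                            "VALVE")
        log_mcu(t, code, if (a$auto) "auto" else "", state$trial_idx)
      } else if (a$kind == "log" && a$code == "STATE") {
        row <- log_mcu(t, "STATE", a$arg, state$trial_idx)
        log_boundary(t, a$arg, state$trial_idx, row)
      } else if (a$kind == "log") {
        log_mcu(t, a$code, a$arg, state$trial_idx)
      }
    }
  }

  send <- function(ev) {
    res <- advance(state, config, ev)
    state <<- res$state
    do_actions(res$actions, ev$time)
  }

  # session start: first epoch of trial 1
  row <- log_mcu(0, "STATE", state$epoch_name, 1L)
  log_boundary(0, state$epoch_name, 1L, row)

  max_ticks <- ceiling(config$session_end$max_duration_min * 60 / dt) + 10
  # encoder stream: preallocated, filled by direct indexing (hot path)
  enc_t_v <- numeric(max_ticks); enc_pos_v <- numeric(max_ticks)
  enc_trial_v <- integer(max_ticks); enc_n <- 0L
  speed_buf <- numeric(0); speed_i <- 0L
  tick <- 0L
  while (!state$session_ended && tick < max_ticks) {
    tick <- tick + 1L
    if (state$trial_idx != planned_trial && !state$in_iti) {
      planned_trial <- state$trial_idx
      plan <- plan_trial(trial_type_now(state))
      truth_rows[[planned_trial]] <- list(
        trial = planned_trial, type = trial_type_now(state),
        response = plan$resp,
        outcome = truth_outcome(config$task_kind, trial_type_now(state),
                                plan$resp),
        t_start = state$t)
    }
    t <- t + dt
    in_dist_epoch <- !state$in_iti &&
      config$epochs[[state$epoch_idx]]$trigger == "distance"
    if (in_dist_epoch) {
      if (speed_i >= length(speed_buf)) {
        speed_buf <- pmax(0, rnorm(4096, policy$speed_mean,
                                   policy$speed_sd))
        speed_i <- 0L
      }
      speed_i <- speed_i + 1L
      send(rig_event("distance_delta", t,
                     delta = speed_buf[speed_i] * dt))
    } else {
      send(rig_event("timer_tick", t, dt = dt))
    }
    if (closed_loop && !state$in_iti && !state$session_ended) {
      enc_n <- enc_n + 1L
      enc_t_v[enc_n] <- t
      enc_pos_v[enc_n] <- if (state$epoch_idx == 1L) state$dist
                          else epoch1_len + state$dist
      enc_trial_v[enc_n] <- state$trial_idx
    }
    if (state$session_ended) break
    if (state$in_iti || state$trial_idx != planned_trial) next

    # agent-driven events for the planned trial
    if (config$task_kind == "two_choice_closed_loop") {
      if (!plan$appr_fired && state$epoch_idx == 1L &&
          state$dist >= plan$appr_pos) {
        plan$appr_fired <- TRUE
        log_mcu(t, if (plan$appr_side == "left") "LICK_L" else "LICK_R",
                "", state$trial_idx)
        send(rig_event(paste0("lick_", plan$appr_side), t))
      }
      if (!plan$fired && state$epoch_idx == 2L &&
          !is.na(plan$lick_pos) && state$dist >= plan$lick_pos) {
        plan$fired <- TRUE
        log_mcu(t, if (plan$resp == "left") "LICK_L" else "LICK_R", "",
                state$trial_idx)
        send(rig_event(paste0("lick_", plan$resp), t))
        plan$next_extra_t <- t + 1 / max(policy$lick_rate, 1e-6)
      }
      if (plan$fired && plan$extra_left < plan$n_extra &&
          !is.na(plan$next_extra_t) && t >= plan$next_extra_t &&
          state$epoch_idx == 2L) {
        plan$extra_left <- plan$extra_left + 1L
        plan$next_extra_t <- t + 1 / max(policy$lick_rate, 1e-6)
        log_mcu(t, if (plan$resp == "left") "LICK_L" else "LICK_R", "",
                state$trial_idx)
        send(rig_event(paste0("lick_", plan$resp), t))
      }
    } else if (config$task_kind %in% c("gonogo_freely_moving",
                                       "fm_shaping_2")) {
      ep <- config$epochs[[state$epoch_idx]]
      if (!plan$init_fired && ep$trigger == "event" &&
          t - state$epoch_t0 >= plan$init_delay) {
        plan$init_fired <- TRUE
        send(rig_event("init_touch", t))
      }
      if (!plan$fired && state$epoch_idx == length(config$epochs) &&
          !is.na(plan$lick_t) &&
          t - state$epoch_t0 >= plan$lick_t) {
        plan$fired <- TRUE
        log_mcu(t, "LICK_L", "", state$trial_idx)
        send(rig_event("lick_left", t))
      }
    } else { # hf_shaping, fm_shaping_1: timer-gated stimulus
      if (!plan$fired && state$epoch_idx == length(config$epochs) &&
          !is.na(plan$lick_t) && t - state$epoch_t0 >= plan$lick_t) {
        plan$fired <- TRUE
        side <- if (config$task_kind == "hf_shaping") plan$resp else "left"
        log_mcu(t, if (side == "left") "LICK_L" else "LICK_R", "",
                state$trial_idx)
        send(rig_event(paste0("lick_", side), t))
      }
    }
  }
  if (!state$session_ended) {
    state$session_ended <- TRUE
    state$end_reason <- "max_duration"
  }
  t_end <- state$t

  # camera frame triggers at 10 Hz over the whole session
  frame_t <- seq(0.1, t_end, by = 0.1)
  frames <- data.frame(t = frame_t, frame = seq_along(frame_t))

  # device clocks applied post hoc from the clocks sub-stream
  set.seed(derive_seed(seed, "clocks"))
  mcu_true <- buf_get(mcu_t)
  device_raw <- cummax(clock_read(rig$mcu, mcu_true) * 1000)
  device_ms <- cummax(round(device_raw))
  mcu_log <- data.frame(device_time = as.integer(device_ms),
                        event_code = buf_get(mcu_code),
                        arg = buf_get(mcu_arg),
                        trial = buf_get(mcu_trial),
                        t_true = mcu_true, stringsAsFactors = FALSE)
  encoder <- data.frame(t = clock_read(rig$program,
                                       enc_t_v[seq_len(enc_n)]),
                        position = enc_pos_v[seq_len(enc_n)],
                        trial = enc_trial_v[seq_len(enc_n)])
  frames$t <- clock_read(rig$program, frames$t)
  boundaries <- data.frame(trial = buf_get(bnd_trial),
                           name = buf_get(bnd_name),
                           t_true = buf_get(bnd_t),
                           mcu_ms = device_raw[buf_get(bnd_row)],
                           prog_s = clock_read(
                             clock_spec(rig$program$offset,
                                        rig$program$drift_ppm, 0,
                                        rig$program$period_ms),
                             buf_get(bnd_t)))

  # ground-truth pupil radius series: AR(1) around 12 px (cosmetic)
  set.seed(derive_seed(seed, "frames"))
  nfr <- nrow(frames)
  rad <- numeric(nfr)
  if (nfr > 0) {
    rad[1] <- 12
    for (i in seq_len(nfr - 1L))
      rad[i + 1L] <- 12 + 0.9 * (rad[i] - 12) + rnorm(1, 0, 0.6)
  }
  truth_trials <- do.call(rbind, lapply(truth_rows, function(r)
    data.frame(trial = r$trial, type = r$type, response = r$response,
               outcome = r$outcome, t_start = r$t_start,
               stringsAsFactors = FALSE)))

  structure(list(
    config = config, policy = policy, rig = rig, seed = seed,
    schedule = schedule, mcu_log = mcu_log, encoder = encoder,
    frames = frames, boundaries = boundaries,
    truth = list(trials = truth_trials,
                 pupil = data.frame(frame = frames$frame, radius = rad)),
    trials = state$trials, end_reason = state$end_reason,
    rewards_n = state$rewards_n, volume_ul = state$volume_ul,
    param_log = state$param_log, duration_s = t_end,
    epoch1_len = epoch1_len), class = "raw_session")
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf(
    "Raw session (%s): %d trials, %d rewards (%.0f ul), end: %s, %.1f s\n",
    x$config$task_kind, length(x$trials), x$rewards_n, x$volume_ul,
    x$end_reason, x$duration_s))
  invisible(x)
}

#' Specify synthetic eye frames
#'
#' Frames are grayscale (0-255). Open frames contain a dark filled disk
#' (the pupil) on a brighter iris/sclera background with additive
#' Gaussian noise; occluded frames additionally draw an eyelid band from
#' the top of the frame covering the pupil by the drawn coverage
#' fraction.
#'
#' @param width,height Frame size in px.
#' @param radius_mean,radius_sd Pupil radius distribution in px.
#' @param center_jitter Pupil center jitter SD in px.
#' @param occlusion_prob Per-frame probability of eyelid occlusion.
#' @param coverage_range Range of the eyelid coverage fraction of the
#'   pupil on occluded frames.
#' @param noise_sd Additive intensity noise SD.
#' @return An object of class `eye_frame_spec`.
#' @export
eye_frame_spec <- function(width = 100L, height = 80L, radius_mean = 12,
                           radius_sd = 2, center_jitter = 3,
                           occlusion_prob = 0.2,
                           coverage_range = c(0.8, 1),
                           noise_sd = 8) {
  stopifnot(occlusion_prob >= 0, occlusion_prob <= 1,
            radius_mean + 3 * radius_sd < min(width, height) / 2)
  structure(list(width = as.integer(width), height = as.integer(height),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 center_jitter = center_jitter,
                 occlusion_prob = occlusion_prob,
                 coverage_range = coverage_range, noise_sd = noise_sd),
            class = "eye_frame_spec")
}

PUPIL_INTENSITY <- 40
IRIS_INTENSITY <- 150
EYELID_INTENSITY <- 185

#' Generate synthetic eye frames with ground truth
#'
#' @param spec An [eye_frame_spec()].
#' @param n Number of frames.
#' @param seed Integer seed.
#' @return List with `frames` (list of `height x width` matrices,
#'   0-255) and `truth` (data frame: `frame`, `label`, `cx`, `cy`,
#'   `radius`, `coverage`).
#' @export
generate_eye_frames <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "eye_frame_spec"), is_count(n))
  with_seed(seed, {
    w <- spec$width; h <- spec$height
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    frames <- vector("list", n)
    truth <- data.frame(frame = seq_len(n),
                        label = character(n), cx = numeric(n),
                        cy = numeric(n), radius = numeric(n),
                        coverage = numeric(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      r <- max(3, rnorm(1, spec$radius_mean, spec$radius_sd))
      cx <- w / 2 + rnorm(1, 0, spec$center_jitter)
      cy <- h / 2 + rnorm(1, 0, spec$center_jitter)
      fr <- matrix(IRIS_INTENSITY, nrow = h, ncol = w)
      fr[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- PUPIL_INTENSITY
      occluded <- runif(1) < spec$occlusion_prob
      cov <- 0
      if (occluded) {
        cov <- runif(1, spec$coverage_range[1], spec$coverage_range[2])
        lid_to <- min(h, ceiling(cy - r + cov * 2 * r))
        fr[seq_len(lid_to), ] <- EYELID_INTENSITY
      }
      if (spec$noise_sd > 0)
        fr <- fr + matrix(rnorm(h * w, 0, spec$noise_sd), nrow = h)
      frames[[i]] <- pmax(pmin(fr, 255), 0)
      truth$label[i] <- if (occluded) "occluded" else "open"
      truth$cx[i] <- cx; truth$cy[i] <- cy
      truth$radius[i] <- r; truth$coverage[i] <- cov
    }
    list(frames = frames, truth = truth)
  })
}

#' Write frames as PNG files
#'
#' @param frames List of grayscale matrices (0-255).
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_frames_png <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(frames)))
  for (i in seq_along(frames))
    png::writePNG(frames[[i]] / 255, paths[i])
  invisible(paths)
}

#' Read a grayscale eye frame (PNG or TIFF)
#'
#' @param path File path.
#' @return Matrix of intensities 0-255 (multi-channel images are
#'   averaged to grayscale).
#' @export
read_frame <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_fmt("reading TIFF frames requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE],
                                           c(1, 2), mean)
  img * 255
}
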