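# Two-clock synchronization: MCU #1 event timestamps and program-clock
# external-device samples are each re-expressed relative to the chosen
# anchor epoch's onset ON THEIR OWN CLOCK; anchor-relative times never
# cross clocks, which is exactly why adding external devices needs no new
# timestamping machinery.

#' Compute velocity from combined encoder samples
#'
#' `v[i] = (x[i] - x[i-1]) / (t[i] - t[i-1])`; the first sample is `NaN`
#' (no previous sample exists). The output shares the input time column.
#'
#' @param encoder_combined Two-column matrix (time s, position cm).
#' @return Two-column matrix (time s, velocity cm/s).
#' @export
#' @examples
#' compute_velocity(cbind(c(0, 1), c(0, 5))) # velocity NaN, 5
compute_velocity <- function(encoder_combined) {
  m <- matrix(as.numeric(encoder_combined), ncol = 2)
  n <- nrow(m)
  if (n == 0L)
    return(two_col(NULL, c("time", "velocity")))
  dt <- diff(m[, 1])
  if (any(dt == 0))
    stop_fmt("duplicate encoder timestamps at indices %s",
             paste(which(dt == 0), collapse = ", "))
  v <- c(NaN, diff(m[, 2]) / dt)
  two_col(cbind(m[, 1], v), c("time", "velocity"))
}

#' Merge camera frame triggers with per-frame pupil radii
#'
#' @param frame_triggers Data frame or matrix with columns time and frame
#'   number.
#' @param radii Data frame with columns `frame` and `radius`.
#' @return List with `frame_combined` and `pupil_radius_combined`
#'   two-column matrices sharing the frame-trigger time column; frames
#'   without a radius carry `NaN`.
#' @export
merge_frames <- function(frame_triggers, radii) {
  ft <- matrix(as.numeric(as.matrix(frame_triggers)), ncol = 2)
  if (nrow(ft) == 0L)
    return(list(frame_combined = two_col(NULL, c("time", "frame")),
                pupil_radius_combined = two_col(NULL, c("time", "radius"))))
  idx <- match(ft[, 2], radii$frame)
  r <- ifelse(is.na(idx), NaN, radii$radius[idx])
  list(frame_combined = two_col(ft, c("time", "frame")),
       pupil_radius_combined = two_col(cbind(ft[, 1], r),
                                       c("time", "radius")))
}

#' Timestamp TTL transitions at the MCU polling rate
#'
#' The MCU reads the TTL line at 300 Hz, so a true edge is reported at
#' the first sampling tick at or after the edge: the reporting latency is
#' in `[0, period)`, i.e. within 3.3 ms at 300 Hz.
#'
#' @param ttl_edges Numeric vector of true edge times in s.
#' @param period Sampling period in s (default 1/300).
#' @return Data frame with `edge`, `reported`, `latency` (s).
#' @export
sample_ttl <- function(ttl_edges, period = 1 / 300) {
  stopifnot(period > 0)
  reported <- ceiling(ttl_edges / period - 1e-12) * period
  data.frame(edge = ttl_edges, reported = reported,
             latency = reported - ttl_edges)
}

MCU_FLAG_MAP <- c(LICK_L = "is_lick_left", LICK_R = "is_lick_right",
                  VALVE_L = "is_reward_triggered",
                  VALVE_R = "is_reward_triggered",
                  VALVE = "is_reward_triggered",
                  MANUAL_OPEN = "is_manual_open")

#' Align one trial's raw streams into a trial record
#'
#' MCU event times are re-expressed relative to the anchor onset on the
#' MCU clock; external-device sample times relative to the anchor onset
#' on the program clock. Pre-onset times are negative; approach-epoch
#' positions become negative distance-to-go.
#'
#' @param trial_id,trial_type Trial identity.
#' @param mcu_events This trial's MCU log rows (`device_time` ms,
#'   `event_code`, `arg`).
#' @param encoder This trial's encoder samples (`t` s program clock,
#'   `position` cm within the trial corridor).
#' @param frames This trial's frame triggers (`t`, `frame`).
#' @param radii Per-frame radii for the session (`frame`, `radius`).
#' @param anchor_mcu_ms Anchor-epoch onset on the MCU clock (ms).
#' @param anchor_prog_s Anchor-epoch onset on the program clock (s).
#' @param anchor Anchor epoch name (the `STATE` argument marking its
#'   onset).
#' @param epoch1_len Length in cm of the pre-anchor (approach) corridor
#'   segment; subtracted from positions so the anchor onset sits at 0.
#' @return A [trial_record()].
#' @export
align_trial <- function(trial_id, trial_type, mcu_events, encoder, frames,
                        radii, anchor_mcu_ms, anchor_prog_s,
                        anchor = "Grating", epoch1_len = 50) {
  if (is.na(anchor_mcu_ms))
    stop_fmt("trial %s: anchor epoch '%s' onset missing", trial_id, anchor)
  keep <- mcu_events$event_code %in% names(MCU_FLAG_MAP) |
    (mcu_events$event_code == "STATE" &
       mcu_events$arg %in% c(anchor, "RewardZone", paste0(anchor, "End")))
  ev <- mcu_events[keep, , drop = FALSE]
  ts <- (ev$device_time - anchor_mcu_ms) / 1000
  n <- length(ts)
  flags <- list(is_lick_left = logical(n), is_lick_right = logical(n),
                is_epoch_start = logical(n),
                is_reward_zone_entry = logical(n),
                is_reward_triggered = logical(n),
                is_epoch_end = logical(n), is_manual_open = logical(n))
  for (i in seq_len(n)) {
    code <- ev$event_code[i]
    f <- if (code == "STATE") {
      if (ev$arg[i] == anchor) "is_epoch_start"
      else if (ev$arg[i] == "RewardZone") "is_reward_zone_entry"
      else "is_epoch_end"
    } else MCU_FLAG_MAP[[code]]
    flags[[f]][i] <- TRUE
  }
  enc <- NULL
  if (!is.null(encoder) && nrow(encoder) > 0)
    enc <- cbind(encoder$t - anchor_prog_s, encoder$position - epoch1_len)
  fr <- NULL; pr <- NULL
  if (!is.null(frames) && nrow(frames) > 0) {
    mf <- merge_frames(cbind(frames$t - anchor_prog_s, frames$frame),
                       radii)
    fr <- mf$frame_combined
    pr <- mf$pupil_radius_combined
  }
  trial_record(trial_id = trial_id, trial_type = trial_type,
               timestamps = ts,
               is_lick_left = flags$is_lick_left,
               is_lick_right = flags$is_lick_right,
               is_epoch_start = flags$is_epoch_start,
               is_reward_zone_entry = flags$is_reward_zone_entry,
               is_reward_triggered = flags$is_reward_triggered,
               is_epoch_end = flags$is_epoch_end,
               is_manual_open = flags$is_manual_open,
               encoder_combined = enc, frame_combined = fr,
               pupil_radius_combined = pr)
}

#' Align a raw simulated session into a session record
#'
#' Applies [align_trial()] to every trial of a [run_session()] output,
#' anchored on the decision epoch. Trials missing their anchor onset are
#' excluded (their count is reported in the session metadata).
#'
#' @param raw A `raw_session` from [run_session()].
#' @param anchor Anchor epoch name; defaults to the decision (last)
#'   epoch of the task.
#' @return A [session_record()] whose `outcomes` come from
#'   [score_trial()]; `meta$n_excluded` counts anchor-less trials.
#' @export
align_session <- function(raw, anchor = NULL) {
  stopifnot(inherits(raw, "raw_session"))
  config <- raw$config
  anchor <- anchor %||% config$epochs[[length(config$epochs)]]$name
  n_tr <- length(raw$trials)
  recs <- list()
  outcomes <- character(0)
  excluded <- 0L
  for (i in seq_len(n_tr)) {
    b <- raw$boundaries[raw$boundaries$trial == i &
                          raw$boundaries$name == anchor, , drop = FALSE]
    if (nrow(b) == 0L) {
      excluded <- excluded + 1L
      message(sprintf("trial %d: anchor '%s' missing; excluded", i,
                      anchor))
      next
    }
    mcu <- raw$mcu_log[raw$mcu_log$trial == i, , drop = FALSE]
    enc <- raw$encoder[raw$encoder$trial == i, , drop = FALSE]
    tr_t0 <- raw$truth$trials$t_start[i]
    tr_t1 <- raw$trials[[i]]$t_end
    frs <- raw$frames[raw$frames$t >= tr_t0 & raw$frames$t <= tr_t1, ,
                      drop = FALSE]
    rec <- align_trial(
      trial_id = length(recs) + 1L,
      trial_type = raw$trials[[i]]$type,
      mcu_events = mcu, encoder = enc, frames = frs,
      radii = raw$truth$pupil,
      anchor_mcu_ms = b$mcu_ms[1], anchor_prog_s = b$prog_s[1],
      anchor = anchor, epoch1_len = raw$epoch1_len)
    recs[[length(recs) + 1L]] <- rec
    outcomes <- c(outcomes, score_trial(raw$trials[[i]], config))
  }
  pl <- if (length(raw$param_log))
    do.call(rbind, lapply(raw$param_log, function(u)
      data.frame(trial = u$trial, parameter = u$parameter,
                 old = as.character(u$old), new = as.character(u$new),
                 stringsAsFactors = FALSE)))
  else NULL
  session_record(
    session_id = sprintf("sim-%s-seed%d", config$task_kind, raw$seed),
    config = list(task_kind = config$task_kind,
                  reward_volume_ul = config$reward_volume_ul,
                  anchor = anchor,
                  session_end = config$session_end),
    trials = recs, param_log = pl,
    meta = list(start_time = "1970-01-01T00:00:00Z",
                end_reason = raw$end_reason,
                reward_count = raw$rewards_n,
                total_volume_ul = raw$volume_ul,
                duration_s = raw$duration_s,
                n_excluded = excluded),
    outcomes = outcomes)
}

#' Benchmark the discrepancy between the two session clocks
#'
#' For every epoch with boundaries visible on both clocks, compares the
#' epoch duration measured on the MCU clock with the duration measured on
#' the program clock. Offsets cancel in durations; drift, jitter and the
#' 300 Hz quantization remain.
#'
#' @param raw A `raw_session` from [run_session()], or a data frame of
#'   boundaries with columns `trial`, `mcu_ms`, `prog_s`.
#' @return List with `mean_ms`, `max_ms` and `n_epochs`.
#' @export
clock_discrepancy <- function(raw) {
  b <- if (inherits(raw, "raw_session")) raw$boundaries else raw
  diffs <- numeric(0)
  for (tr in unique(b$trial)) {
    bt <- b[b$trial == tr, , drop = FALSE]
    if (nrow(bt) < 2L) next
    d_mcu <- diff(bt$mcu_ms)
    d_prog <- diff(bt$prog_s) * 1000
    diffs <- c(diffs, abs(d_mcu - d_prog))
  }
  if (!length(diffs)) return(list(mean_ms = NA_real_, max_ms = NA_real_,
                                  n_epochs = 0L))
  list(mean_ms = mean(diffs), max_ms = max(diffs),
       n_epochs = length(diffs))
}
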