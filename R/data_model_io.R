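# Standardized per-trial output structure and session artifacts:
# a session is (a) one tab-separated MCU event log on the lick-port
# controller's millisecond clock and (b) a directory of per-trial JSON
# records whose field names mirror the platform's original MATLAB struct
# (TrialID, TrialType, NoOfTimestamps, ...) for interoperability.

MCU_EVENT_CODES <- c("LICK_L", "LICK_R", "VALVE_L", "VALVE_R", "VALVE",
                     "STATE", "INIT_TOUCH", "TTL_HIGH", "TTL_LOW",
                     "MANUAL_OPEN", "CLICK")

# internal (snake_case) field -> serialized (struct-compatible) field
TRIAL_FIELD_MAP <- c(
  trial_id = "TrialID", trial_type = "TrialType",
  n_timestamps = "NoOfTimestamps", timestamps = "Timestamps",
  is_lick_left = "isLickLeft", is_lick_right = "isLickRight",
  is_epoch_start = "isGratingStart",
  is_reward_zone_entry = "isRewardZoneEntry",
  is_reward_triggered = "isRewardTriggered",
  is_epoch_end = "isGratingEnd", is_manual_open = "isManualOpen",
  encoder_combined = "encoderData_combined", velocity = "Velocity",
  frame_combined = "frameData_combined",
  pupil_radius_combined = "pupilRadius_combined")

FLAG_FIELDS <- c("is_lick_left", "is_lick_right", "is_epoch_start",
                 "is_reward_zone_entry", "is_reward_triggered",
                 "is_epoch_end", "is_manual_open")

two_col <- function(x, names) {
  if (is.null(x) || length(x) == 0L)
    x <- matrix(numeric(0), ncol = 2)
  x <- matrix(as.numeric(x), ncol = 2)
  colnames(x) <- names
  x
}

#' Construct a standardized per-trial record
#'
#' The per-trial output structure of the platform: MCU-clock event
#' timestamps (aligned to the anchor-epoch onset, negative before onset),
#' one boolean flag vector per event kind, and the external-device arrays
#' sampled on the program clock (encoder position, derived velocity, camera
#' frame triggers, pupil radii). Each timestamp exists because exactly one
#' event occurred, so per index exactly one flag is set.
#'
#' @param trial_id Positive integer trial number.
#' @param trial_type Label string (e.g. `"vertical"`, `"angled"`, `"go"`).
#' @param timestamps Numeric vector of event times in s relative to the
#'   anchor-epoch onset.
#' @param is_lick_left,is_lick_right,is_epoch_start,is_reward_zone_entry,is_reward_triggered,is_epoch_end,is_manual_open
#'   Logical flag vectors, each the length of `timestamps`.
#' @param encoder_combined Two-column matrix (time s, position cm); the
#'   approach epoch carries negative positions (distance left to travel).
#' @param velocity Two-column matrix (time s, velocity cm/s) sharing the
#'   encoder time column; first velocity value is `NaN`. Computed with
#'   [compute_velocity()] when omitted.
#' @param frame_combined Two-column matrix (time s, frame number).
#' @param pupil_radius_combined Two-column matrix (time s, radius px).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, trial_type, timestamps = numeric(0),
                         is_lick_left = logical(0),
                         is_lick_right = logical(0),
                         is_epoch_start = logical(0),
                         is_reward_zone_entry = logical(0),
                         is_reward_triggered = logical(0),
                         is_epoch_end = logical(0),
                         is_manual_open = logical(0),
                         encoder_combined = NULL, velocity = NULL,
                         frame_combined = NULL,
                         pupil_radius_combined = NULL) {
  enc <- two_col(encoder_combined, c("time", "position"))
  if (is.null(velocity) && nrow(enc) > 0)
    velocity <- compute_velocity(enc)
  rec <- structure(list(
    trial_id = as.integer(trial_id), trial_type = as.character(trial_type),
    n_timestamps = length(timestamps), timestamps = as.numeric(timestamps),
    is_lick_left = as.logical(is_lick_left),
    is_lick_right = as.logical(is_lick_right),
    is_epoch_start = as.logical(is_epoch_start),
    is_reward_zone_entry = as.logical(is_reward_zone_entry),
    is_reward_triggered = as.logical(is_reward_triggered),
    is_epoch_end = as.logical(is_epoch_end),
    is_manual_open = as.logical(is_manual_open),
    encoder_combined = enc,
    velocity = two_col(velocity, c("time", "velocity")),
    frame_combined = two_col(frame_combined, c("time", "frame")),
    pupil_radius_combined = two_col(pupil_radius_combined,
                                    c("time", "radius"))),
    class = "trial_record")
  rec
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "Trial %d (%s): %d event timestamps, %d encoder samples, %d frames\n",
    x$trial_id, x$trial_type, x$n_timestamps, nrow(x$encoder_combined),
    nrow(x$frame_combined)))
  invisible(x)
}

#' Construct a session record
#'
#' @param session_id Identifier string.
#' @param config Snapshot of the task configuration (a [task_config()] or
#'   plain list).
#' @param trials List of [trial_record()] objects with dense increasing
#'   trial ids starting at 1.
#' @param param_log Data frame of within-session parameter changes
#'   (`trial`, `parameter`, `old`, `new`).
#' @param meta List with `start_time`, `end_reason` (one of
#'   `max_rewards`, `max_duration`, `manual`), `reward_count`,
#'   `total_volume_ul`.
#' @param outcomes Optional character vector of per-trial outcome labels.
#' @return An object of class `session_record`.
#' @export
session_record <- function(session_id, config = list(), trials = list(),
                           param_log = NULL, meta = list(),
                           outcomes = NULL) {
  if (is.null(param_log))
    param_log <- data.frame(trial = integer(0), parameter = character(0),
                            old = character(0), new = character(0),
                            stringsAsFactors = FALSE)
  structure(list(session_id = as.character(session_id), config = config,
                 trials = trials, param_log = param_log, meta = meta,
                 outcomes = outcomes),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session %s: %d trials, %s rewards, end reason: %s\n",
              x$session_id, length(x$trials),
              x$meta$reward_count %||% "?", x$meta$end_reason %||% "?"))
  invisible(x)
}

#' Write an MCU event log
#'
#' Tab-separated text, one line per event
#' (`<device_time_ms>\t<event_code>\t<arg>`) under a `# mcu_log v1` header.
#' Times are integer milliseconds on the MCU clock and must be
#' non-decreasing.
#'
#' @param events Data frame with columns `device_time` (integer ms),
#'   `event_code` (one of the log's enumerated codes) and `arg`
#'   (free string, may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mcu_log <- function(events, path) {
  events <- as_mcu_events(events)
  if (nrow(events) > 1L) {
    bad <- which(diff(events$device_time) < 0)
    if (length(bad))
      stop_fmt("events out of time order at index %d", bad[1] + 1L)
  }
  lines <- c("# mcu_log v1",
             sprintf("%d\t%s\t%s", events$device_time, events$event_code,
                     events$arg))
  writeLines(lines, path)
  invisible(path)
}

as_mcu_events <- function(events) {
  if (is.null(events) || (is.data.frame(events) && nrow(events) == 0L) ||
      (is.list(events) && !is.data.frame(events) && length(events) == 0L))
    return(data.frame(device_time = integer(0), event_code = character(0),
                      arg = character(0), stringsAsFactors = FALSE))
  if (!is.data.frame(events)) events <- do.call(rbind.data.frame, events)
  stopifnot(all(c("device_time", "event_code", "arg") %in% names(events)))
  bad <- setdiff(unique(events$event_code), MCU_EVENT_CODES)
  if (length(bad)) stop_fmt("unknown event_code(s): %s",
                            paste(bad, collapse = ", "))
  data.frame(device_time = as.integer(round(events$device_time)),
             event_code = as.character(events$event_code),
             arg = as.character(events$arg), stringsAsFactors = FALSE)
}

#' Parse an MCU event log
#'
#' Exact inverse of [write_mcu_log()].
#'
#' @param path File in the `mcu_log v1` dialect.
#' @return Data frame with columns `device_time`, `event_code`, `arg`.
#' @export
parse_mcu_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "# mcu_log v1")
    stop_fmt("%s: missing 'mcu_log v1' header", path)
  body <- lines[-1]
  out <- data.frame(device_time = integer(length(body)),
                    event_code = character(length(body)),
                    arg = character(length(body)), stringsAsFactors = FALSE)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L) parts <- c(parts, "")
    t <- suppressWarnings(as.integer(parts[1]))
    if (length(parts) != 3L || is.na(t))
      stop_fmt("%s: malformed line %d", path, i + 1L)
    if (!parts[2] %in% MCU_EVENT_CODES)
      stop_fmt("%s: unknown event_code '%s' on line %d", path, parts[2],
               i + 1L)
    out$device_time[i] <- t
    out$event_code[i] <- parts[2]
    out$arg[i] <- parts[3]
  }
  out
}

# --- JSON encoding with a NaN-safe dialect -------------------------------
# JSON has no NaN literal; not-a-number is serialized as the string "NaN".

encode_num <- function(x) {
  x <- as.numeric(x)
  if (!any(is.nan(x))) return(x)
  lapply(x, function(v) if (is.nan(v)) "NaN" else v)
}

decode_num <- function(x) {
  if (is.list(x))
    return(vapply(x, function(v)
      if (identical(v, "NaN")) NaN else as.numeric(v), numeric(1)))
  out <- suppressWarnings(as.numeric(x))
  out[!is.na(x) & x == "NaN"] <- NaN
  out
}

encode_mat <- function(m) {
  if (nrow(m) == 0L) return(list(col1 = numeric(0), col2 = numeric(0)))
  list(col1 = encode_num(m[, 1]), col2 = encode_num(m[, 2]))
}

decode_mat <- function(x, names) {
  two_col(cbind(decode_num(x$col1), decode_num(x$col2)), names)
}

trial_to_json_list <- function(rec) {
  out <- list()
  for (f in names(TRIAL_FIELD_MAP)) {
    v <- rec[[f]]
    out[[TRIAL_FIELD_MAP[[f]]]] <-
      if (is.matrix(v)) encode_mat(v)
      else if (is.numeric(v)) encode_num(v)
      else v
  }
  out
}

trial_from_json_list <- function(x, trial_label = "?") {
  miss <- setdiff(unname(TRIAL_FIELD_MAP), names(x))
  if (length(miss))
    stop_fmt("trial %s: missing required field(s): %s", trial_label,
             paste(miss, collapse = ", "))
  trial_record(
    trial_id = x$TrialID, trial_type = x$TrialType,
    timestamps = decode_num(x$Timestamps),
    is_lick_left = as.logical(unlist(x$isLickLeft) %||% logical(0)),
    is_lick_right = as.logical(unlist(x$isLickRight) %||% logical(0)),
    is_epoch_start = as.logical(unlist(x$isGratingStart) %||% logical(0)),
    is_reward_zone_entry =
      as.logical(unlist(x$isRewardZoneEntry) %||% logical(0)),
    is_reward_triggered =
      as.logical(unlist(x$isRewardTriggered) %||% logical(0)),
    is_epoch_end = as.logical(unlist(x$isGratingEnd) %||% logical(0)),
    is_manual_open = as.logical(unlist(x$isManualOpen) %||% logical(0)),
    encoder_combined = decode_mat(x$encoderData_combined,
                                  c("time", "position")),
    velocity = decode_mat(x$Velocity, c("time", "velocity")),
    frame_combined = decode_mat(x$frameData_combined, c("time", "frame")),
    pupil_radius_combined = decode_mat(x$pupilRadius_combined,
                                       c("time", "radius")))
}

#' Write a session as a per-trial record directory
#'
#' Writes `session.json` (metadata, config snapshot, parameter-change log,
#' outcomes) plus one `trial_NNNN.json` per trial using the platform's
#' struct-compatible field names. Round-trips losslessly through
#' [read_trial_records()]; `NaN` is serialized as the JSON string `"NaN"`.
#'
#' @param session A [session_record()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_records <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(session_id = session$session_id,
               n_trials = length(session$trials),
               config = session$config,
               param_log = session$param_log,
               meta = session$meta,
               outcomes = session$outcomes)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       dataframe = "columns")
  for (i in seq_along(session$trials))
    jsonlite::write_json(trial_to_json_list(session$trials[[i]]),
                         file.path(dir, sprintf("trial_%04d.json", i)),
                         auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(dir)
}

#' Read a per-trial record directory
#'
#' @param dir Directory written by [write_trial_records()].
#' @return A [session_record()].
#' @export
read_trial_records <- function(dir) {
  sf <- file.path(dir, "session.json")
  if (!file.exists(sf)) stop_fmt("%s: no session.json found", dir)
  meta <- jsonlite::read_json(sf, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  n <- meta$n_trials %||% 0L
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    tf <- file.path(dir, sprintf("trial_%04d.json", i))
    if (!file.exists(tf)) stop_fmt("trial %d: file %s missing", i, tf)
    x <- jsonlite::read_json(tf, simplifyVector = TRUE)
    trials[[i]] <- trial_from_json_list(x, trial_label = as.character(i))
  }
  pl <- meta$param_log
  if (is.null(pl) || length(pl) == 0L) pl <- NULL
  session_record(session_id = meta$session_id,
                 config = meta$config %||% list(),
                 trials = trials, param_log = pl,
                 meta = meta$meta %||% list(),
                 outcomes = meta$outcomes)
}

violation <- function(trial_id, rule, message) {
  data.frame(trial_id = trial_id, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate the invariants of a session record
#'
#' Checks every per-trial invariant of the record structure (flag lengths,
#' one-event-per-timestamp, single anchor onset, shared velocity/encoder
#' time column, `NaN` first velocity sample, strictly increasing frame
#' numbers) plus session-level rules (dense increasing trial ids, reward
#' volume conservation, known end reason).
#'
#' @param session A [session_record()].
#' @return A data frame of violations (`trial_id`, `rule`, `message`);
#'   zero rows if and only if the session is valid.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_record"))
  v <- list()
  add <- function(x) v[[length(v) + 1L]] <<- x
  ids <- vapply(session$trials, function(tr) tr$trial_id, integer(1))
  if (length(ids) && !identical(ids, seq_along(ids)))
    add(violation(NA_integer_, "trial_ids_dense",
                  "trial ids must be dense and increasing from 1"))
  er <- session$meta$end_reason
  if (!is.null(er) && !er %in% c("max_rewards", "max_duration", "manual"))
    add(violation(NA_integer_, "end_reason",
                  sprintf("unknown end reason '%s'", er)))
  vol <- session$config$reward_volume_ul %||% NULL
  if (!is.null(vol) && !is.null(session$meta$reward_count) &&
      !is.null(session$meta$total_volume_ul) &&
      abs(session$meta$reward_count * vol -
          session$meta$total_volume_ul) > 1e-6)
    add(violation(NA_integer_, "volume_conservation",
                  "reward count x reward volume != total volume"))
  for (tr in session$trials) {
    id <- tr$trial_id
    n <- tr$n_timestamps
    for (f in FLAG_FIELDS)
      if (length(tr[[f]]) != n)
        add(violation(id, "flag_length",
                      sprintf("%s has length %d, expected %d", f,
                              length(tr[[f]]), n)))
    if (all(vapply(FLAG_FIELDS, function(f) length(tr[[f]]) == n,
                   logical(1))) && n > 0) {
      nset <- rowSums(vapply(FLAG_FIELDS, function(f) tr[[f]],
                             logical(n)))
      if (any(nset == 0))
        add(violation(id, "event_per_timestamp",
                      sprintf("%d timestamp(s) with no event flag set",
                              sum(nset == 0))))
      if (any(nset > 1))
        add(violation(id, "event_per_timestamp",
                      sprintf("%d timestamp(s) with multiple flags set",
                              sum(nset > 1))))
    }
    if (length(tr$is_epoch_start) == n && sum(tr$is_epoch_start) > 1)
      add(violation(id, "single_anchor",
                    "more than one anchor-epoch start flagged"))
    nv <- nrow(tr$velocity)
    if (nv != nrow(tr$encoder_combined))
      add(violation(id, "velocity_rows",
                    "velocity and encoder must have the same samples"))
    else if (nv > 0) {
      if (!isTRUE(all.equal(tr$velocity[, 1], tr$encoder_combined[, 1])))
        add(violation(id, "velocity_time_column",
                      "velocity must share the encoder time column"))
      if (!is.nan(tr$velocity[1, 2]))
        add(violation(id, "velocity_first_nan",
                      "first velocity sample must be NaN"))
    }
    fr <- tr$frame_combined[, 2]
    if (length(fr) > 1 && any(diff(fr) <= 0))
      add(violation(id, "frames_increasing",
                    "frame numbers must be strictly increasing"))
  }
  # frame numbers must also increase across trials
  allf <- unlist(lapply(session$trials, function(tr) tr$frame_combined[, 2]))
  if (length(allf) > 1 && any(diff(allf) <= 0))
    add(violation(NA_integer_, "frames_increasing",
                  "frame numbers must increase across trials"))
  if (!length(v))
    return(violation(integer(0), character(0), character(0)))
  do.call(rbind, v)
}

event_name_at <- function(tr, i) {
  for (f in FLAG_FIELDS) if (isTRUE(tr[[f]][i])) return(f)
  NA_character_
}

#' Export a session as long-format CSV files
#'
#' Writes `events.csv` (one row per MCU event timestamp: `trial_id`,
#' `time`, `event`) and `trial_summary.csv` (`trial_id`, `type`, `outcome`,
#' `n_licks_left`, `n_licks_right`, `rewarded`).
#'
#' @param session A [session_record()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_session_csv <- function(session, dir) {
  stopifnot(inherits(session, "session_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- lapply(session$trials, function(tr) {
    if (tr$n_timestamps == 0L)
      return(NULL)
    data.frame(trial_id = tr$trial_id, time = tr$timestamps,
               event = vapply(seq_len(tr$n_timestamps),
                              function(i) event_name_at(tr, i),
                              character(1)),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(trial_id = integer(0), time = numeric(0),
                     event = character(0))
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  outc <- session$outcomes
  summ <- lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    data.frame(trial_id = tr$trial_id, type = tr$trial_type,
               outcome = if (!is.null(outc) && i <= length(outc))
                 outc[i] else NA_character_,
               n_licks_left = sum(tr$is_lick_left),
               n_licks_right = sum(tr$is_lick_right),
               rewarded = any(tr$is_reward_triggered),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  if (is.null(summ))
    summ <- data.frame(trial_id = integer(0), type = character(0),
                       outcome = character(0), n_licks_left = integer(0),
                       n_licks_right = integer(0), rewarded = logical(0))
  write.csv(summ, file.path(dir, "trial_summary.csv"), row.names = FALSE)
  invisible(dir)
}
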