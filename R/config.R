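# Declarative task configuration: ordered epochs, trial-type schedule,
# reward contingencies, session-end rules, and the parameters that may be
# adjusted within a session at trial boundaries.

#' Specify one epoch of a trial
#'
#' An epoch is a subsection of a trial with its own stimulus and rules.
#' Its end is triggered by accumulated locomotion distance, a timer, or a
#' sensor event.
#'
#' @param name Epoch name (e.g. `"Approach"`, `"Grating"`).
#' @param trigger One of `"distance"`, `"timer"`, `"event"`.
#' @param value Trigger value: length in cm (`distance`), duration in s
#'   (`timer`), or sensor name (`event`, e.g. `"init_touch"`).
#' @param stimulus Stimulus tag carried as metadata (`"per_trial"` means
#'   the scheduled trial type selects the stimulus).
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(name, trigger = c("distance", "timer", "event"),
                       value, stimulus = NA_character_) {
  trigger <- match.arg(trigger)
  if (trigger %in% c("distance", "timer")) {
    if (!is.numeric(value) || value <= 0)
      stop_fmt("epoch '%s': %s trigger value must be > 0", name, trigger)
    value <- as.numeric(value)
  } else value <- as.character(value)
  structure(list(name = name, trigger = trigger, value = value,
                 stimulus = stimulus), class = "epoch_spec")
}

#' Construct a task configuration
#'
#' @param task_kind One of `two_choice_closed_loop`, `hf_shaping`,
#'   `fm_shaping_1`, `fm_shaping_2`, `gonogo_freely_moving`.
#' @param epochs Ordered list of [epoch_spec()] objects.
#' @param schedule A [schedule_spec()] (or `NULL` for single-type tasks).
#' @param contingency Data frame with columns `trial_type`, `correct_side`,
#'   `reward_port`, `volume_ul` mapping each trial type to its rewarded
#'   response.
#' @param reward_zone For closed-loop tasks, `c(open =, close =)` distances
#'   in cm within the decision epoch: licking can trigger reward from
#'   `open` on, and automatic delivery (when enabled) fires at `close`.
#'   Defaults to the central two thirds of the decision epoch.
#' @param response_delay Go/No-go delay in s after decision-epoch onset
#'   before a lick can trigger reward (default 0.5; licks during the delay
#'   still count for outcome scoring).
#' @param stimulus_duration Stimulus presentation time in s for
#'   timer-gated decision epochs.
#' @param iti Intertrial interval in s; the platform floor is 0.05 s.
#' @param session_end List `max_rewards`, `max_duration_min`; the session
#'   ends at whichever is reached first.
#' @param adjustable Within-session adjustable parameters: `auto_water`,
#'   `x_left`, `x_right` (three-drop boosting per side), `autoclicker`,
#'   `side_bias_rule`, `consecutive_limit`.
#' @param auto_release_delay For shaping tasks, s after stimulus change at
#'   which an automatic reward is released when enabled (default 2).
#' @param prestim_delay_range For the first freely moving shaping stage,
#'   range in s of the random pre-stimulus delay.
#' @param stimulus_timeout Fallback decision-epoch timeout in s for epochs
#'   that otherwise wait for a lick.
#' @param reward_volume_ul Drop volume in microliters.
#' @param stimulus_meta Free-form stimulus metadata (carried, not
#'   rendered), e.g. grating spatial frequency in cycles/degree.
#' @return An object of class `task_config`.
#' @seealso [task_preset()] for the bundled paradigms.
#' @export
task_config <- function(task_kind = c("two_choice_closed_loop", "hf_shaping",
                                      "fm_shaping_1", "fm_shaping_2",
                                      "gonogo_freely_moving"),
                        epochs, schedule = NULL, contingency = NULL,
                        reward_zone = NULL, response_delay = 0.5,
                        stimulus_duration = 4, iti = 2,
                        session_end = list(max_rewards = 125,
                                           max_duration_min = 90),
                        adjustable = list(), auto_release_delay = 2,
                        prestim_delay_range = c(0.5, 3),
                        stimulus_timeout = 60,
                        reward_volume_ul = 6,
                        stimulus_meta = list()) {
  task_kind <- match.arg(task_kind)
  stopifnot(is.list(epochs), length(epochs) > 0,
            all(vapply(epochs, inherits, logical(1), "epoch_spec")))
  if (iti < 0.05)
    stop_fmt("iti %.3f s below the 50 ms platform floor", iti)
  if (reward_volume_ul <= 0) stop_fmt("reward volume must be > 0")
  dec <- epochs[[length(epochs)]]
  if (is.null(reward_zone) && dec$trigger == "distance")
    reward_zone <- reward_zone_bounds(dec$value)
  if (!is.null(reward_zone)) {
    names(reward_zone) <- c("open", "close")
    if (!(reward_zone[["open"]] < reward_zone[["close"]]))
      stop_fmt("reward zone must open before the auto-delivery distance")
    if (dec$trigger == "distance" && reward_zone[["close"]] >= dec$value)
      stop_fmt("auto-delivery distance must lie inside the decision epoch")
  }
  adj <- utils::modifyList(
    list(auto_water = FALSE, x_left = FALSE, x_right = FALSE,
         autoclicker = FALSE, side_bias_rule = FALSE,
         consecutive_limit = if (is.null(schedule)) NA_integer_
                             else schedule$max_consecutive),
    adjustable)
  if (!is.null(contingency))
    stopifnot(all(c("trial_type", "reward_port", "volume_ul") %in%
                  names(contingency)), all(contingency$volume_ul > 0))
  structure(list(task_kind = task_kind, epochs = epochs,
                 schedule = schedule, contingency = contingency,
                 reward_zone = reward_zone,
                 response_delay = response_delay,
                 stimulus_duration = stimulus_duration, iti = iti,
                 session_end = session_end, adjustable = adj,
                 auto_release_delay = auto_release_delay,
                 prestim_delay_range = prestim_delay_range,
                 stimulus_timeout = stimulus_timeout,
                 reward_volume_ul = reward_volume_ul,
                 stimulus_meta = stimulus_meta),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("Task config '%s': %d epoch(s) [%s]\n", x$task_kind,
              length(x$epochs),
              paste(vapply(x$epochs, `[[`, character(1), "name"),
                    collapse = " -> ")))
  cat(sprintf("  drop volume %g ul; session ends at %d rewards or %g min\n",
              x$reward_volume_ul, x$session_end$max_rewards,
              x$session_end$max_duration_min))
  invisible(x)
}

#' Bundled task presets
#'
#' Ready-made configurations for the five paradigms:
#' \describe{
#'   \item{two_choice}{Head-fixed closed-loop two-choice visual
#'     discrimination. 50 cm approach epoch then 50 cm grating epoch;
#'     vertical gratings reward left licks, 135-degree angled gratings
#'     reward right licks (6 ul drops); stimulus probabilities 0.5/0.5
#'     with at most 3 consecutive repeats; reward zone opens at ~8.33 cm
#'     and automatic delivery (when enabled) fires at ~41.67 cm; 2 s ITI;
#'     session ends at 125 rewards (~750 ul) or 90 min.}
#'   \item{hf_shaping}{Head-fixed acclimation: 20 cm travel gate, then a
#'     6 s black-or-white full-screen stimulus; the first lick at either
#'     port is rewarded from that port; optional automatic release 2 s
#'     after stimulus change; side-bias deterrent rule active.}
#'   \item{fm_shaping_1}{Freely moving acclimation stage 1: random
#'     0.5-3 s delay, then white-circle stimulus; a lick is rewarded
#'     (4 ul) and the stimulus ends 0.5 s later.}
#'   \item{fm_shaping_2}{Stage 2 adds trial self-initiation via the
#'     initiation sensor and a 0.5 s ITI.}
#'   \item{gonogo}{Freely moving Go/No-go luminance discrimination:
#'     self-initiated trials, 4 s stimulus, Go probability 0.3 with at
#'     most 10 consecutive repeats, 0.5 s response delay, 0.5 s ITI,
#'     4 ul drops; session ends at 190 rewards (~750 ul) or 120 min.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored in the preset's schedule spec.
#' @param n_trials Length of the generated schedule (defaults generously
#'   above the reward budget so the schedule never runs out).
#' @return A [task_config()].
#' @export
#' @examples
#' task_preset("two_choice")
task_preset <- function(name = c("two_choice", "hf_shaping", "fm_shaping_1",
                                 "fm_shaping_2", "gonogo"),
                        seed = 1L, n_trials = NULL) {
  name <- match.arg(name)
  switch(name,
    two_choice = task_config(
      "two_choice_closed_loop",
      epochs = list(
        epoch_spec("Approach", "distance", 50, stimulus = "circles"),
        epoch_spec("Grating", "distance", 50, stimulus = "per_trial")),
      schedule = schedule_spec(n_trials %||% 400L,
                               c(vertical = 0.5, angled = 0.5),
                               max_consecutive = 3L, seed = seed),
      contingency = data.frame(
        trial_type = c("vertical", "angled"),
        correct_side = c("left", "right"),
        reward_port = c("left", "right"), volume_ul = c(6, 6),
        stringsAsFactors = FALSE),
      iti = 2, reward_volume_ul = 6,
      session_end = list(max_rewards = 125L, max_duration_min = 90),
      stimulus_meta = list(spatial_frequency_cpd = 0.04,
                           orientations_deg = c(vertical = 0, angled = 135))),
    hf_shaping = task_config(
      "hf_shaping",
      epochs = list(
        epoch_spec("Gate", "distance", 20, stimulus = "gray"),
        epoch_spec("Stimulus", "timer", 6, stimulus = "black_or_white")),
      schedule = schedule_spec(n_trials %||% 400L,
                               c(black = 0.5, white = 0.5),
                               max_consecutive = 400L, seed = seed),
      contingency = data.frame(
        trial_type = c("black", "white"),
        correct_side = c("either", "either"),
        reward_port = c("licked", "licked"), volume_ul = c(6, 6),
        stringsAsFactors = FALSE),
      iti = 2, reward_volume_ul = 6, stimulus_duration = 6,
      adjustable = list(side_bias_rule = TRUE),
      session_end = list(max_rewards = 125L, max_duration_min = 90)),
    fm_shaping_1 = task_config(
      "fm_shaping_1",
      epochs = list(
        epoch_spec("Delay", "timer", 3, stimulus = "gray"),
        epoch_spec("Stimulus", "timer", 60, stimulus = "white_circles")),
      schedule = schedule_spec(n_trials %||% 700L, c(go = 1),
                               max_consecutive = 700L, seed = seed),
      contingency = data.frame(
        trial_type = "go", correct_side = "center",
        reward_port = "center", volume_ul = 4, stringsAsFactors = FALSE),
      iti = 0.5, reward_volume_ul = 4, response_delay = 0,
      session_end = list(max_rewards = 190L, max_duration_min = 90)),
    fm_shaping_2 = task_config(
      "fm_shaping_2",
      epochs = list(
        epoch_spec("Prestim", "event", "init_touch", stimulus = "gray"),
        epoch_spec("Stimulus", "timer", 60, stimulus = "white_circles")),
      schedule = schedule_spec(n_trials %||% 700L, c(go = 1),
                               max_consecutive = 700L, seed = seed),
      contingency = data.frame(
        trial_type = "go", correct_side = "center",
        reward_port = "center", volume_ul = 4, stringsAsFactors = FALSE),
      iti = 0.5, reward_volume_ul = 4, response_delay = 0,
      session_end = list(max_rewards = 190L, max_duration_min = 90)),
    gonogo = task_config(
      "gonogo_freely_moving",
      epochs = list(
        epoch_spec("Prestim", "event", "init_touch", stimulus = "gray"),
        epoch_spec("Decision", "timer", 4, stimulus = "per_trial")),
      schedule = schedule_spec(n_trials %||% 2000L,
                               c(go = 0.3, nogo = 0.7),
                               max_consecutive = 10L, seed = seed),
      contingency = data.frame(
        trial_type = c("go", "nogo"),
        correct_side = c("center", "none"),
        reward_port = c("center", "none"), volume_ul = c(4, 4),
        stringsAsFactors = FALSE),
      iti = 0.5, reward_volume_ul = 4, response_delay = 0.5,
      stimulus_duration = 4,
      session_end = list(max_rewards = 190L, max_duration_min = 120)))
}

# --- minimal TOML reader -------------------------------------------------
# Supports the subset the bundled presets use: [dotted.table] headers,
# key = string | number | boolean | flat array. No installed R package
# parses TOML, and the presets need nothing more.

parse_toml_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- substr(s, 2, nchar(s) - 1)
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value)))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop_fmt("cannot parse TOML value: %s", s)
}

read_toml <- function(path) {
  lines <- readLines(path)
  out <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".",
                          fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop_fmt("%s: malformed TOML line %d", path, i)
    key <- trimws(substr(line, 1, eq - 1))
    val <- parse_toml_value(substr(line, eq + 1, nchar(line)))
    path_keys <- c(section, key)
    out <- assign_nested(out, path_keys, val)
  }
  out
}

assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1L) { lst[[keys]] <- value; return(lst) }
  head <- keys[1]
  lst[[head]] <- assign_nested(lst[[head]] %||% list(), keys[-1], value)
  lst
}

#' Read a task configuration from a TOML file
#'
#' Reads the declarative config dialect used by the bundled presets under
#' `inst/extdata/configs/` and builds the corresponding [task_config()].
#'
#' @param path Path to a `.toml` config.
#' @param seed Seed for the schedule spec (overrides the file's value).
#' @return A [task_config()].
#' @export
#' @examples
#' p <- system.file("extdata", "configs", "gonogo.toml",
#'                  package = "operantr")
#' read_task_config(p)
read_task_config <- function(path, seed = NULL) {
  x <- read_toml(path)
  sched <- NULL
  if (!is.null(x$schedule)) {
    probs <- as.numeric(x$schedule$probs)
    names(probs) <- x$schedule$labels
    sched <- schedule_spec(x$schedule$n_trials, probs,
                           max_consecutive = x$schedule$max_consecutive,
                           seed = seed %||% x$schedule$seed %||% 1L)
  }
  eps <- x$epochs
  ord <- order(vapply(eps, function(e) e$order, numeric(1)))
  epochs <- lapply(unname(eps[ord]), function(e)
    epoch_spec(e$name, e$trigger, e$value,
               stimulus = e$stimulus %||% NA_character_))
  cont <- NULL
  if (!is.null(x$contingency)) {
    cont <- do.call(rbind, lapply(names(x$contingency), function(tt) {
      e <- x$contingency[[tt]]
      data.frame(trial_type = tt, correct_side = e$correct_side,
                 reward_port = e$reward_port, volume_ul = e$volume_ul,
                 stringsAsFactors = FALSE)
    }))
  }
  args <- list(task_kind = x$task_kind, epochs = epochs, schedule = sched,
               contingency = cont)
  for (f in c("response_delay", "stimulus_duration", "iti",
              "auto_release_delay", "stimulus_timeout",
              "reward_volume_ul"))
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  if (!is.null(x$session_end)) args$session_end <- x$session_end
  if (!is.null(x$adjustable)) args$adjustable <- x$adjustable
  if (!is.null(x$reward_zone))
    args$reward_zone <- c(open = x$reward_zone$open,
                          close = x$reward_zone$close)
  if (!is.null(x$stimulus_meta)) args$stimulus_meta <- x$stimulus_meta
  do.call(task_config, args)
}
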