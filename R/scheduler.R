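#' Specify a constrained random trial-type schedule
#'
#' A schedule draws each trial's type independently from `type_probs`,
#' subject to a maximum-run constraint: no type may occur more than
#' `max_consecutive` times in a row. The two bundled paradigms use
#' 50/50 stimulus probabilities with a run limit of 3 (head-fixed
#' two-choice task) and 30/70 with a run limit of 10 (freely moving
#' Go/No-go task).
#'
#' @param n_trials Positive integer, schedule length.
#' @param type_probs Named numeric vector of type probabilities; must sum
#'   to 1 (tolerance 1e-9).
#' @param max_consecutive Positive integer run limit.
#' @param seed Integer seed making the schedule reproducible.
#' @return An object of class `schedule_spec`.
#' @seealso [generate_schedule()]
#' @export
#' @examples
#' schedule_spec(100, c(go = 0.3, nogo = 0.7), max_consecutive = 10, seed = 1)
schedule_spec <- function(n_trials, type_probs, max_consecutive = 3L,
                          seed = 1L) {
  if (!is_count(n_trials) || n_trials < 1)
    stop_fmt("n_trials must be a positive integer")
  if (is.null(names(type_probs)) || any(names(type_probs) == ""))
    stop_fmt("type_probs must be a fully named vector")
  if (any(type_probs < 0) || abs(sum(type_probs) - 1) > 1e-9)
    stop_fmt("type_probs must be non-negative and sum to 1 (got %.12f)",
             sum(type_probs))
  if (!is_count(max_consecutive) || max_consecutive < 1)
    stop_fmt("max_consecutive must be >= 1")
  structure(
    list(n_trials = as.integer(n_trials), type_probs = type_probs,
         max_consecutive = as.integer(max_consecutive),
         seed = as.integer(seed)),
    class = "schedule_spec")
}

#' Generate a trial-type schedule at session start
#'
#' Draws the whole schedule before the session begins. The run constraint
#' is enforced by a forced flip: when a draw would create a run of
#' `max_consecutive + 1` identical types, the draw is redone among the
#' remaining types with probabilities renormalized. This alters the next
#' trial's stimulus rather than rejecting whole schedules, so generation
#' is O(n); it slightly inflates the frequency of minority types when the
#' constraint binds often (documented, not corrected).
#'
#' @param spec A [schedule_spec()].
#' @return Character vector of trial-type labels, length `spec$n_trials`.
#' @export
#' @examples
#' s <- generate_schedule(schedule_spec(20, c(vertical = 0.5, angled = 0.5),
#'                                      max_consecutive = 3, seed = 42))
#' max_run_length(s)
generate_schedule <- function(spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  labels <- names(spec$type_probs)
  probs <- as.numeric(spec$type_probs)
  n <- spec$n_trials
  if (length(labels) == 1L) {
    if (n > spec$max_consecutive)
      stop_fmt("single trial type with max_consecutive=%d < n_trials=%d: run constraint unsatisfiable",
               spec$max_consecutive, n)
    return(rep(labels, n))
  }
  with_seed(spec$seed, {
    out <- character(n)
    run <- 0L
    last <- NA_character_
    for (i in seq_len(n)) {
      draw <- sample(labels, 1L, prob = probs)
      if (!is.na(last) && draw == last && run >= spec$max_consecutive) {
        keep <- labels != last
        draw <- if (sum(keep) == 1L) labels[keep]
                else sample(labels[keep], 1L, prob = probs[keep])
      }
      if (!is.na(last) && draw == last) run <- run + 1L else run <- 1L
      last <- draw
      out[i] <- draw
    }
    out
  })
}

#' Longest constant run in a schedule
#'
#' @param schedule Vector of labels.
#' @return Integer length of the longest run of identical labels; 0 for an
#'   empty schedule.
#' @export
#' @examples
#' max_run_length(c("A", "A", "B")) # 2
max_run_length <- function(schedule) {
  if (length(schedule) == 0L) return(0L)
  max(rle(as.character(schedule))$lengths)
}

#' Empirical trial-type frequencies of a schedule
#'
#' @param schedule Non-empty vector of labels.
#' @return Named numeric vector of proportions (sums to 1).
#' @export
empirical_frequencies <- function(schedule) {
  if (length(schedule) == 0L) stop_fmt("empty schedule")
  tab <- table(as.character(schedule))
  structure(as.numeric(tab) / length(schedule), names = names(tab))
}
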