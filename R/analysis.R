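#' Proportion with 1/(2N) correction for extreme rates
#'
#' Hit and false-alarm rates of 0 or 1 make the z-transform infinite. The
#' standard correction replaces 0 with `1/(2n)` and 1 with `1 - 1/(2n)`;
#' all other rates are the plain proportion `k/n`.
#'
#' @param k Number of "yes" trials (non-negative integer).
#' @param n Number of trials (positive integer).
#' @return Corrected proportion in (0, 1).
#' @export
#' @examples
#' rate_correction(0, 20)  # 0.025
#' rate_correction(10, 20) # 0.5
rate_correction <- function(k, n) {
  if (!is_count(n) || n == 0) stop_fmt("rate undefined for n = 0")
  if (!is_count(k) || k > n) stop_fmt("need 0 <= k <= n")
  if (k == 0) return(1 / (2 * n))
  if (k == n) return(1 - 1 / (2 * n))
  k / n
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = z(hit rate) - z(false-alarm rate)`, with `z` the inverse of the
#' standard normal cumulative distribution function.
#'
#' @param hit_rate,fa_rate Rates strictly inside (0, 1); apply
#'   [rate_correction()] first when counts can be extreme.
#' @return Sensitivity in z-units.
#' @export
#' @examples
#' dprime(0.8, 0.2)
dprime <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1) || any(fa_rate <= 0 | fa_rate >= 1))
    stop_fmt("rates must lie strictly inside (0, 1)")
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Side-bias index (signed decision criterion)
#'
#' The signed criterion `-(z(hit) + z(fa)) / 2` under the left-lick-positive
#' convention (hit = left lick on a left-rewarded trial, false alarm = left
#' lick on a right-rewarded trial). Positive values indicate a bias toward
#' licking right, negative values a bias toward licking left; bias-correction
#' thresholds are applied to the absolute value.
#'
#' @inheritParams dprime
#' @return Signed criterion in z-units.
#' @export
#' @examples
#' bias_index(0.8, 0.8) # -0.8416, left bias
bias_index <- function(hit_rate, fa_rate) {
  if (any(hit_rate <= 0 | hit_rate >= 1) || any(fa_rate <= 0 | fa_rate >= 1))
    stop_fmt("rates must lie strictly inside (0, 1)")
  -(qnorm(hit_rate) + qnorm(fa_rate)) / 2
}

#' Reward-zone / central-two-thirds geometry of a linear epoch
#'
#' The decision zone of the closed-loop corridor task is the central two
#' thirds of the 50 cm grating epoch: it opens at 50/6 cm (~8.33 cm, where
#' licking can first trigger reward) and closes at 250/6 cm (~41.67 cm, the
#' automatic-delivery distance). Epoch discrimination uses the same central
#' two thirds of each epoch.
#'
#' @param epoch_length Epoch length in cm (default 50).
#' @return Named numeric vector `c(open =, close =)` in cm.
#' @export
#' @examples
#' round(reward_zone_bounds(50), 2) # 8.33, 41.67
reward_zone_bounds <- function(epoch_length = 50) {
  stopifnot(epoch_length > 0)
  c(open = epoch_length / 6, close = 5 * epoch_length / 6)
}

new_performance_summary <- function(counts, hit_rate, fa_rate, dprime_grating,
                                    dprime_epoch = NA_real_,
                                    bias = NA_real_, n_scored, session_id = NA,
                                    paradigm, extra = list()) {
  structure(c(list(
    counts = counts, hit_rate = hit_rate, fa_rate = fa_rate,
    dprime_grating = dprime_grating, dprime_epoch = dprime_epoch,
    bias_index = bias, n_scored = n_scored, session_id = session_id,
    paradigm = paradigm), extra),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Performance summary (%s)\n", x$paradigm))
  cat("  outcomes:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                           collapse = ", "), "\n")
  cat(sprintf("  hit rate %.3f, false-alarm rate %.3f (corrected)\n",
              x$hit_rate, x$fa_rate))
  cat(sprintf("  d' = %.3f", x$dprime_grating))
  if (!is.na(x$dprime_epoch)) cat(sprintf(", epoch d' = %.3f", x$dprime_epoch))
  if (!is.na(x$bias_index)) cat(sprintf(", side-bias index = %+.3f",
                                        x$bias_index))
  cat("\n")
  invisible(x)
}

#' Summarize a two-choice closed-loop session
#'
#' Computes grating discrimination and epoch discrimination. Grating
#' discrimination: hit rate is the proportion of vertical trials scored
#' `hit_vertical` out of vertical trials with an in-zone lick
#' (`hit_vertical` + `fa_vertical`); the false-alarm rate is the proportion
#' of angled trials scored `fa_angled` out of angled trials with an in-zone
#' lick. Trials without an in-zone lick (`no_interaction`) are excluded.
#' Epoch discrimination: the hit rate is the proportion of trials with at
#' least one lick in the central two thirds of the grating epoch, the
#' false-alarm rate the same for the approach epoch. All rates pass through
#' [rate_correction()] before the z-transform.
#'
#' @param outcomes Character vector of per-trial outcome labels from
#'   [score_trial()]: `hit_vertical`, `fa_vertical`, `hit_angled`,
#'   `fa_angled`, `no_interaction`.
#' @param lick_positions List (one element per trial) of numeric corridor
#'   positions of lick events, in cm relative to grating onset (approach
#'   epoch negative, grating epoch positive). Needed for epoch
#'   discrimination; may be `NULL` to skip it.
#' @param epoch_length Epoch length in cm (default 50).
#' @param session_id Optional identifier carried into the summary.
#' @return A `performance_summary` object. When one stimulus class has no
#'   scored trials the grating d-prime is `NA` and the unscored counts are
#'   reported in `missing`.
#' @export
summarize_two_choice <- function(outcomes, lick_positions = NULL,
                                 epoch_length = 50, session_id = NA) {
  labs <- c("hit_vertical", "fa_vertical", "hit_angled", "fa_angled",
            "no_interaction")
  bad <- setdiff(unique(outcomes), labs)
  if (length(bad)) stop_fmt("unknown outcome label(s): %s",
                            paste(bad, collapse = ", "))
  counts <- vapply(labs, function(l) sum(outcomes == l), integer(1))
  n_v <- counts[["hit_vertical"]] + counts[["fa_vertical"]]
  n_a <- counts[["hit_angled"]] + counts[["fa_angled"]]
  if (n_v > 0 && n_a > 0) {
    h <- rate_correction(counts[["hit_vertical"]], n_v)
    f <- rate_correction(counts[["fa_angled"]], n_a)
    dp <- dprime(h, f)
    bi <- bias_index(h, f)
  } else {
    h <- f <- dp <- bi <- NA_real_
  }
  dp_epoch <- eh <- ef <- NA_real_
  if (!is.null(lick_positions)) {
    if (length(lick_positions) != length(outcomes))
      stop_fmt("lick_positions must have one element per trial")
    zone <- reward_zone_bounds(epoch_length)
    in_grating <- vapply(lick_positions, function(p)
      any(p >= zone[["open"]] & p < zone[["close"]]), logical(1))
    in_approach <- vapply(lick_positions, function(p)
      any(p >= zone[["open"]] - epoch_length &
          p < zone[["close"]] - epoch_length), logical(1))
    n <- length(outcomes)
    if (n > 0) {
      eh <- rate_correction(sum(in_grating), n)
      ef <- rate_correction(sum(in_approach), n)
      dp_epoch <- dprime(eh, ef)
    }
  }
  new_performance_summary(
    counts = counts, hit_rate = h, fa_rate = f, dprime_grating = dp,
    dprime_epoch = dp_epoch, bias = bi, n_scored = n_v + n_a,
    session_id = session_id, paradigm = "two_choice",
    extra = list(epoch_hit_rate = eh, epoch_fa_rate = ef,
                 missing = if (n_v == 0 || n_a == 0) counts else NULL))
}

#' Summarize a Go/No-go session
#'
#' Hit rate = hits / (hits + misses); false-alarm rate =
#' false alarms / (false alarms + correct rejects); d-prime via [dprime()]
#' after [rate_correction()].
#'
#' @param outcomes Character vector with labels `hit`, `miss`,
#'   `false_alarm`, `correct_reject`.
#' @param session_id Optional identifier.
#' @return A `performance_summary` object.
#' @export
summarize_gonogo <- function(outcomes, session_id = NA) {
  labs <- c("hit", "miss", "false_alarm", "correct_reject")
  bad <- setdiff(unique(outcomes), labs)
  if (length(bad)) stop_fmt("unknown outcome label(s): %s",
                            paste(bad, collapse = ", "))
  if (length(outcomes) == 0L) stop_fmt("empty session: no outcomes to score")
  counts <- vapply(labs, function(l) sum(outcomes == l), integer(1))
  n_go <- counts[["hit"]] + counts[["miss"]]
  n_ng <- counts[["false_alarm"]] + counts[["correct_reject"]]
  if (n_go == 0 || n_ng == 0)
    stop_fmt("need at least one Go and one No-go trial")
  h <- rate_correction(counts[["hit"]], n_go)
  f <- rate_correction(counts[["false_alarm"]], n_ng)
  new_performance_summary(
    counts = counts, hit_rate = h, fa_rate = f,
    dprime_grating = dprime(h, f), n_scored = length(outcomes),
    session_id = session_id, paradigm = "gonogo")
}

#' Sliding-window performance within a session
#'
#' One summary per window end position `i` in `window..n`, stride 1; empty
#' when fewer trials than the window length.
#'
#' @param outcomes Per-trial outcome labels (Go/No-go labels, or two-choice
#'   labels with `paradigm = "two_choice"`).
#' @param window Window length in trials (default 100).
#' @param paradigm `"gonogo"` or `"two_choice"`.
#' @return A data frame with one row per window (`end`, `hit_rate`,
#'   `fa_rate`, `dprime`), zero rows when `length(outcomes) < window`.
#' @export
sliding_performance <- function(outcomes, window = 100L,
                                paradigm = c("gonogo", "two_choice")) {
  paradigm <- match.arg(paradigm)
  n <- length(outcomes)
  ends <- if (n >= window) seq.int(window, n) else integer(0)
  rows <- lapply(ends, function(i) {
    o <- outcomes[(i - window + 1L):i]
    s <- tryCatch(
      if (paradigm == "gonogo") summarize_gonogo(o)
      else summarize_two_choice(o),
      error = function(e) NULL)
    data.frame(end = i,
               hit_rate = if (is.null(s)) NA_real_ else s$hit_rate,
               fa_rate = if (is.null(s)) NA_real_ else s$fa_rate,
               dprime = if (is.null(s)) NA_real_ else s$dprime_grating)
  })
  if (!length(rows))
    return(data.frame(end = integer(0), hit_rate = numeric(0),
                      fa_rate = numeric(0), dprime = numeric(0)))
  do.call(rbind, rows)
}

#' First learned session under the windowed d-prime criterion
#'
#' A subject is considered to have learned on the first session of a
#' `window`-session stretch in which at least `min_above` sessions have
#' d-prime above `threshold`.
#'
#' @param dprimes Numeric vector of per-session d-prime values.
#' @param threshold Criterion value (default 1.5).
#' @param window Window length in sessions (default 3).
#' @param min_above Minimum qualifying sessions per window (default 2).
#' @param strict If `TRUE` (default) a session qualifies when
#'   `d' > threshold`; if `FALSE`, when `d' >= threshold`.
#' @return The 1-based session number, or `NA_integer_` when no window
#'   qualifies.
#' @export
#' @examples
#' learning_session(c(0, 0, 2, 2, 0)) # 2
learning_session <- function(dprimes, threshold = 1.5, window = 3L,
                             min_above = 2L, strict = TRUE) {
  n <- length(dprimes)
  if (n < window) return(NA_integer_)
  above <- if (strict) dprimes > threshold else dprimes >= threshold
  for (s in seq_len(n - window + 1L))
    if (sum(above[s:(s + window - 1L)]) >= min_above) return(s)
  NA_integer_
}

#' Multi-session side-bias correction controller
#'
#' Watches the per-session side-bias index and decides the reward policy
#' for the next session. A bias index above `+engage` (right bias) starts
#' boosting the left port (three drops per rewarded left trial, `x_left`);
#' below `-engage` boosts the right port. Boosting continues until at least
#' `n_reduced` consecutive sessions have `|index| < reduced`, after which
#' rewards are re-equalized; thereafter no action unless the threshold is
#' crossed again.
#'
#' @param indices Numeric vector of per-session side-bias indices, in
#'   session order.
#' @param engage Engagement threshold on `|index|` (default 1).
#' @param reduced Bias-reduced threshold on `|index|` (default 0.25).
#' @param n_reduced Consecutive sub-threshold sessions required (default 2).
#' @return Character vector, one action per observed session, each the
#'   decision taken after that session: `none`, `boost_left`,
#'   `boost_right`, or `re_equalize`.
#' @export
#' @examples
#' bias_controller(c(1.2, 0.2, 0.2)) # boost_left, boost_left, re_equalize
bias_controller <- function(indices, engage = 1, reduced = 0.25,
                            n_reduced = 2L) {
  actions <- character(length(indices))
  boosting <- NA_character_
  streak <- 0L
  for (i in seq_along(indices)) {
    x <- indices[i]
    if (is.na(boosting)) {
      actions[i] <- if (x > engage) "boost_left"
                    else if (x < -engage) "boost_right"
                    else "none"
      if (actions[i] != "none") { boosting <- actions[i]; streak <- 0L }
    } else {
      streak <- if (abs(x) < reduced) streak + 1L else 0L
      if (streak >= n_reduced) {
        actions[i] <- "re_equalize"
        boosting <- NA_character_
        streak <- 0L
      } else actions[i] <- boosting
    }
  }
  actions
}
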