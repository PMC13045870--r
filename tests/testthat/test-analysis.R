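# Independent oracle for the z-transform: numerical inversion of the
# normal CDF by bisection (never uses qnorm).
z_oracle <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(x) stats::pnorm(x) - pp, c(-10, 10),
                   tol = 1e-10)$root, numeric(1))
}

test_that("rate correction replaces extreme proportions by 1/(2N)", {
  expect_equal(rate_correction(10, 20), 0.5)
  expect_equal(rate_correction(0, 20), 0.025)
  expect_equal(rate_correction(20, 20), 0.975)
  expect_error(rate_correction(1, 0), "n = 0")
})

test_that("d-prime matches an independent normal-CDF inversion", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.8, 0.2), z_oracle(0.8) - z_oracle(0.2),
               tolerance = 1e-6)
  expect_equal(dprime(0.8, 0.2), 1.6832, tolerance = 1e-4)
  # pnorm(2) = 0.97725 (closed form)
  expect_equal(dprime(0.97725, 0.5), 2, tolerance = 1e-4)
  expect_error(dprime(1, 0.5), "inside")
})

test_that("d-prime is antisymmetric and monotone in its rates", {
  grid <- seq(0.05, 0.95, by = 0.09)
  for (h in grid) for (f in grid)
    expect_equal(dprime(h, f), -dprime(f, h))
  h <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(dprime(h, 0.2)) > 0))
  expect_true(all(diff(dprime(0.8, h)) < 0))
})

test_that("side-bias index carries the left/right sign convention", {
  expect_equal(bias_index(0.5, 0.5), 0)
  # high left-lick rates on both trial types: bias toward left, negative
  expect_equal(bias_index(0.8, 0.8), -z_oracle(0.8), tolerance = 1e-6)
  expect_equal(bias_index(0.8, 0.8), -0.8416, tolerance = 1e-4)
  expect_equal(bias_index(0.2, 0.2), +0.8416, tolerance = 1e-4)
  # symmetric in its arguments; sign flips under rate complementing
  grid <- seq(0.1, 0.9, by = 0.16)
  for (h in grid) for (f in grid) {
    expect_equal(bias_index(h, f), bias_index(f, h))
    expect_equal(bias_index(1 - h, 1 - f), -bias_index(h, f))
  }
})

test_that("two-choice summary applies the exclusion and correction rules", {
  out <- c(rep("hit_vertical", 10), rep("hit_angled", 10))
  s <- summarize_two_choice(out)
  expect_equal(s$hit_rate, 0.95)
  expect_equal(s$fa_rate, 0.05)
  expect_equal(s$dprime_grating, 2 * z_oracle(0.95), tolerance = 1e-6)
  expect_equal(s$dprime_grating, 3.2897, tolerance = 1e-4)
  expect_equal(sum(s$counts), length(out))

  # all no-interaction: d-prime undefined, reported missing with counts
  s2 <- summarize_two_choice(rep("no_interaction", 5))
  expect_true(is.na(s2$dprime_grating))
  expect_equal(sum(s2$missing), 5)

  # epoch discrimination from lick positions: licks only in the grating
  # zone give maximally separated corrected rates
  pos <- replicate(6, 20, simplify = FALSE) # 20 cm: inside [8.33, 41.67)
  s3 <- summarize_two_choice(rep(c("hit_vertical", "hit_angled"), 3), pos)
  expect_equal(s3$epoch_hit_rate, 1 - 1 / 12)
  expect_equal(s3$epoch_fa_rate, 1 / 12)
  expect_error(summarize_two_choice("banana"), "unknown outcome")
})

test_that("go/no-go summary computes corrected hit and false-alarm rates", {
  out <- c(rep("hit", 30), rep("correct_reject", 70))
  s <- summarize_gonogo(out)
  expect_equal(s$hit_rate, 59 / 60)
  expect_equal(s$fa_rate, 1 / 140)
  expect_equal(s$dprime_grating, z_oracle(59 / 60) - z_oracle(1 / 140),
               tolerance = 1e-6)
  s2 <- summarize_gonogo(rep(c("hit", "miss", "false_alarm",
                               "correct_reject"), 5))
  expect_equal(s2$dprime_grating, 0)
  expect_error(summarize_gonogo(character(0)), "empty")
})

test_that("sliding window yields one summary per end position", {
  out <- rep(c("hit", "false_alarm", "correct_reject"), length.out = 99)
  expect_equal(nrow(sliding_performance(out, 100)), 0)
  out100 <- rep(c("hit", "miss", "false_alarm", "correct_reject"), 25)
  sw <- sliding_performance(out100, 100)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$end, 100)
  set.seed(4)
  out300 <- sample(c("hit", "miss", "false_alarm", "correct_reject"),
                   300, replace = TRUE, prob = c(0.4, 0.1, 0.1, 0.4))
  sw3 <- sliding_performance(out300, 100)
  expect_equal(nrow(sw3), 201)
  expect_lt(max(sw3$dprime) - min(sw3$dprime), 1.5) # flat within noise
})

test_that("learning-session rule picks the first qualifying window", {
  expect_equal(learning_session(c(2, 2, 2)), 1L)
  expect_equal(learning_session(c(0, 0, 2, 2, 0)), 2L)
  expect_true(is.na(learning_session(c(0, 0, 0))))
  expect_true(is.na(learning_session(c(2, 2)))) # shorter than window
  # strictness: values equal to the threshold only count when strict=FALSE
  expect_true(is.na(learning_session(c(1.5, 1.5, 1.5))))
  expect_equal(learning_session(c(1.5, 1.5, 1.5), strict = FALSE), 1L)
})

test_that("learning-session agrees with brute-force window enumeration", {
  brute <- function(d, thr = 1.5, w = 3L, m = 2L) {
    for (s in seq_len(max(0, length(d) - w + 1L)))
      if (sum(d[s:(s + w - 1L)] > thr) >= m) return(s)
    NA_integer_
  }
  set.seed(21)
  for (k in 1:1000) {
    d <- stats::runif(sample(3:12, 1), 0, 3)
    expect_identical(learning_session(d), brute(d))
  }
})

test_that("bias controller boosts until two sub-threshold sessions", {
  expect_identical(bias_controller(1.2), "boost_left")
  expect_identical(bias_controller(c(1.2, 0.2, 0.2)),
                   c("boost_left", "boost_left", "re_equalize"))
  expect_identical(bias_controller(c(0.5, 0.5, 0.5)),
                   c("none", "none", "none"))
  expect_identical(bias_controller(-1.3), "boost_right")
  # non-consecutive sub-threshold sessions restart the count
  expect_identical(bias_controller(c(1.5, 0.1, 0.8, 0.1, 0.1)),
                   c("boost_left", "boost_left", "boost_left",
                     "boost_left", "re_equalize"))
  # threshold crossed again after re-equalization
  expect_identical(bias_controller(c(1.5, 0.1, 0.1, -1.2)),
                   c("boost_left", "boost_left", "re_equalize",
                     "boost_right"))
})

test_that("reward-zone geometry is the central two-thirds of the epoch", {
  b <- reward_zone_bounds(50)
  expect_equal(unname(b), c(50 / 6, 250 / 6))
  expect_lt(b[["open"]], b[["close"]])
})
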