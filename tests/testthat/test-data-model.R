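test_that("MCU log writes the v1 dialect and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mcu_log(NULL, f)
  expect_identical(readLines(f), "# mcu_log v1")

  ev1 <- data.frame(device_time = 1000L, event_code = "LICK_L", arg = "")
  write_mcu_log(ev1, f)
  expect_identical(readLines(f), c("# mcu_log v1", "1000\tLICK_L\t"))
  expect_identical(parse_mcu_log(f), ev1)

  set.seed(12)
  n <- 1000
  ev <- data.frame(
    device_time = sort(sample.int(1e6, n)),
    event_code = sample(c("LICK_L", "LICK_R", "VALVE_L", "VALVE_R",
                          "STATE", "TTL_HIGH", "TTL_LOW", "MANUAL_OPEN"),
                        n, replace = TRUE),
    arg = sample(c("", "Grating", "auto"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  write_mcu_log(ev, f)
  expect_identical(parse_mcu_log(f), ev)
})

test_that("MCU log rejects disorder, bad codes and malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- data.frame(device_time = c(10L, 5L), event_code = "LICK_L",
                    arg = "")
  expect_error(write_mcu_log(bad, f), "index 2")
  expect_error(write_mcu_log(
    data.frame(device_time = 1L, event_code = "NOPE", arg = ""), f),
    "unknown event_code")
  writeLines(c("# mcu_log v1", "12\tLICK_L\t", "oops"), f)
  expect_error(parse_mcu_log(f), "line 3")
  writeLines(c("# mcu_log v1", "12\tWHAT\t"), f)
  expect_error(parse_mcu_log(f), "unknown event_code")
  writeLines("1000\tLICK_L\t", f)
  expect_error(parse_mcu_log(f), "header")
})

test_that("a zero-trial session writes only session metadata", {
  d <- withr::local_tempdir()
  s <- session_record("empty", meta = list(end_reason = "manual",
                                           reward_count = 0,
                                           total_volume_ul = 0))
  write_trial_records(s, d)
  expect_identical(list.files(d), "session.json")
  s2 <- read_trial_records(d)
  expect_length(s2$trials, 0)
})

test_that("trial JSON uses the struct-compatible field names", {
  d <- withr::local_tempdir()
  rec <- trial_record(1, "vertical", timestamps = c(-0.2, 0, 0.5),
                      is_lick_left = c(TRUE, FALSE, FALSE),
                      is_epoch_start = c(FALSE, TRUE, FALSE),
                      is_reward_triggered = c(FALSE, FALSE, TRUE),
                      is_lick_right = logical(3),
                      is_reward_zone_entry = logical(3),
                      is_epoch_end = logical(3),
                      is_manual_open = logical(3),
                      encoder_combined = cbind(c(-0.5, 0, 0.5),
                                               c(-8, 0, 7)))
  s <- session_record("one", trials = list(rec),
                      meta = list(end_reason = "manual"))
  write_trial_records(s, d)
  j <- jsonlite::read_json(file.path(d, "trial_0001.json"))
  expect_true(all(c("TrialID", "TrialType", "NoOfTimestamps",
                    "isLickLeft", "isGratingStart", "Velocity",
                    "encoderData_combined", "pupilRadius_combined")
                  %in% names(j)))
  # NaN is serialized as the string "NaN"
  expect_identical(j$Velocity$col2[[1]], "NaN")
})

test_that("a simulated session round-trips losslessly", {
  d <- withr::local_tempdir()
  s <- shared_aligned_session()
  write_trial_records(s, d)
  s2 <- read_trial_records(d)
  expect_length(s2$trials, length(s$trials))
  for (i in seq_along(s$trials))
    expect_equal(unclass(s2$trials[[i]]), unclass(s$trials[[i]]),
                 tolerance = 0)
  expect_identical(s2$outcomes, s$outcomes)
  expect_error(read_trial_records(file.path(d, "nope")), "session.json")
})

test_that("missing required trial fields are named in the error", {
  d <- withr::local_tempdir()
  s <- session_record("one",
                      trials = list(trial_record(1, "go", numeric(0))),
                      meta = list(end_reason = "manual"))
  write_trial_records(s, d)
  j <- jsonlite::read_json(file.path(d, "trial_0001.json"))
  j$isLickLeft <- NULL
  jsonlite::write_json(j, file.path(d, "trial_0001.json"),
                       auto_unbox = TRUE)
  expect_error(read_trial_records(d), "isLickLeft")
})

test_that("session validation reports injected invariant defects", {
  s <- shared_aligned_session()
  expect_equal(nrow(validate_session(s)), 0)

  # flag vector shorter than the timestamp count
  s_bad <- s
  s_bad$trials[[1]]$is_lick_left <- logical(0)
  r <- validate_session(s_bad)
  expect_true(any(r$rule == "flag_length" & r$trial_id == 1))

  # non-NaN first velocity sample violates the first-sample rule
  s_bad2 <- s
  s_bad2$trials[[2]]$velocity[1, 2] <- 0
  r2 <- validate_session(s_bad2)
  expect_true(any(r2$rule == "velocity_first_nan" & r2$trial_id == 2))

  # a timestamp with two flags set
  s_bad3 <- s
  i <- which(s_bad3$trials[[1]]$is_lick_left)[1]
  if (is.na(i)) i <- 1L
  s_bad3$trials[[1]]$is_manual_open[i] <- TRUE
  expect_true(any(validate_session(s_bad3)$rule == "event_per_timestamp"))

  # broken reward-volume conservation
  s_bad4 <- s
  s_bad4$meta$total_volume_ul <- s_bad4$meta$total_volume_ul + 1
  expect_true(any(validate_session(s_bad4)$rule == "volume_conservation"))
})

test_that("CSV export row counts match the record contents", {
  d <- withr::local_tempdir()
  s0 <- session_record("empty", meta = list(end_reason = "manual"))
  export_session_csv(s0, d)
  expect_equal(nrow(utils::read.csv(file.path(d, "events.csv"))), 0)

  s <- shared_aligned_session()
  export_session_csv(s, d)
  ev <- utils::read.csv(file.path(d, "events.csv"))
  expect_equal(nrow(ev),
               sum(vapply(s$trials, function(tr) tr$n_timestamps,
                          integer(1))))
  summ <- utils::read.csv(file.path(d, "trial_summary.csv"))
  expect_equal(nrow(summ), length(s$trials))
  expect_equal(summ$n_licks_left,
               vapply(s$trials, function(tr) sum(tr$is_lick_left),
                      integer(1)))
})
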