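test_that("write/read round-trips a log at printed precision", {
  log <- make_temp_log(days = 1, value = function(ts, ch) {
    round(25 + as.numeric(ts - ts[1]) / 86400, 4)
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_temp_log(log, path)
  back <- read_temp_log(path)
  expect_equal(back$channels, log$channels)
  expect_equal(back$records$timestamp, log$records$timestamp)
  for (ch in log$channels) {
    expect_equal(back$records[[ch]], round(log$records[[ch]], 4))
  }
  expect_equal(nrow(log_gaps(back)), 0)
})

test_that("out-of-plausibility readings are dropped and counted", {
  log <- make_temp_log(days = 1, channels = c("living_top", "incubator"))
  path <- withr::local_tempfile(fileext = ".csv")
  log$records$living_top[5] <- 85.0
  write_temp_log(log, path)
  back <- read_temp_log(path)
  expect_identical(back$n_dropped, 1L)
  expect_true(is.na(back$records$living_top[5]))
  expect_false(is.na(back$records$incubator[5]))
})

test_that("unknown headers and bad timestamps are handled as specified", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Timestamp;Mystery Sensor",
               "2022-04-01 00:00:00;25.0"), path)
  err <- expect_error(read_temp_log(path), class = "thermocol_header_error")
  expect_match(conditionMessage(err), "Living Top")

  writeLines(c("Timestamp;Living Top",
               "2022-04-01 00:00:00;25.0",
               "not-a-time;25.1",
               "2022-04-01 00:02:00;25.2"), path)
  expect_warning(back <- read_temp_log(path), "skipped 1")
  expect_identical(back$n_skipped_rows, 1L)
  expect_equal(nrow(back$records), 2)
})

test_that("alias headers map onto canonical channels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Timestamp;T_LT;T_CB;T_Inc",
               "2022-04-01 00:00:00;25.0;24.5;26.0"), path)
  back <- read_temp_log(path)
  expect_setequal(back$channels, c("living_top", "control_bottom", "incubator"))
})

test_that("merging is order-insensitive, deduplicating, and associative", {
  mk <- function(start, days) make_temp_log(days = days, start = start)
  a <- mk("2022-04-01", 2)
  b <- mk("2022-04-03", 2)
  c_ <- mk("2022-04-05", 1)
  ab <- merge_temp_logs(a, b)
  expect_equal(nrow(ab$records), nrow(a$records) + nrow(b$records))
  expect_true(all(diff(as.numeric(ab$records$timestamp)) > 0))
  expect_equal(merge_temp_logs(b, a)$records, ab$records)
  expect_equal(merge_temp_logs(merge_temp_logs(a, b), c_)$records,
               merge_temp_logs(a, merge_temp_logs(b, c_))$records)
  # duplicate rows collapse to one
  expect_equal(nrow(merge_temp_logs(a, a)$records), nrow(a$records))
})

test_that("merging logs with different channel sets fails loudly", {
  a <- make_temp_log(channels = c("living_top", "living_bottom"))
  b <- make_temp_log(channels = c("living_top", "incubator"))
  err <- expect_error(merge_temp_logs(a, b), class = "thermocol_merge_error")
  expect_match(conditionMessage(err), "incubator")
})

test_that("a hole between merged weeks appears in the gap report", {
  a <- make_temp_log(days = 1, start = "2022-04-01")
  b <- make_temp_log(days = 1, start = "2022-04-02")
  # remove the first 2 h of week B
  b$records <- b$records[b$records$timestamp >=
                           as.POSIXct("2022-04-02 02:00:00", tz = "UTC"), ]
  b <- temp_log(b$records, sampling_period = 60)
  gaps <- log_gaps(merge_temp_logs(a, b))
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$duration, 2 * 3600 + 60)
})

test_that("valid-day accounting follows the coverage rule", {
  log <- make_temp_log(days = 3)
  sched <- phase_schedule()
  for (ph in analysis_phases(sched)) {
    expect_equal(valid_days(log, ph, sched)$count, 3)
  }
  # delete day 2's D1 interval
  day_of <- as.Date(format(log$records$timestamp, "%Y-%m-%d"))
  lt <- as.POSIXlt(log$records$timestamp)
  mins <- lt$hour * 60 + lt$min
  cut <- !(day_of == as.Date("2022-04-02") & mins >= 480 & mins < 930)
  log2 <- temp_log(log$records[cut, ], sampling_period = 60)
  expect_equal(valid_days(log2, "D1", sched)$count, 2)
  expect_equal(valid_days(log2, "N1", sched)$count, 3)
  expect_false(as.Date("2022-04-02") %in% valid_days(log2, "D1", sched)$days)
})

test_that("full strictness marks a day with one missing sample invalid", {
  log <- make_temp_log(days = 1)
  keep <- seq_len(nrow(log$records)) != 500  # one N1-region sample on day 1
  stopifnot(format(log$records$timestamp[500], "%H") %in% c("08"))
  log2 <- temp_log(log$records[keep, ], sampling_period = 60)
  expect_equal(valid_days(log2, "D1", min_coverage = 1)$count, 0)
  expect_equal(valid_days(log, "D1", min_coverage = 1)$count, 1)
})

test_that("empty datasets yield zero valid days", {
  log <- make_temp_log(days = 1)
  log$records <- log$records[0, ]
  empty <- temp_log(log$records, sampling_period = 60)
  vd <- valid_days(empty, "D1")
  expect_equal(vd$count, 0)
  expect_length(vd$days, 0)
})
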