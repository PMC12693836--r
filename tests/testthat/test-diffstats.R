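test_that("difference series are pointwise minuend minus subtrahend", {
  log <- make_temp_log(days = 1, value = c(living_top = 25.5, living_bottom = 25,
                                           control_top = 25, control_bottom = 25))
  ds <- difference_series(log, "tb_int_living")
  expect_true(all(ds$samples$value == 0.5))
  dc <- difference_series(log, "tb_int_control")
  expect_true(all(dc$samples$value == 0))
  expect_equal(nrow(ds$samples), nrow(log$records))
})

test_that("swapping the channel pair negates the series", {
  set.seed(11)
  log <- make_temp_log(days = 1,
                       channels = c("living_top", "control_top"),
                       value = function(ts, ch) 25 + rnorm(length(ts), 0, 0.3))
  fwd <- difference_series(log, "top")$samples$value
  # reverse pair built by renaming channels
  rec <- log$records
  names(rec)[names(rec) == "living_top"] <- "tmp"
  names(rec)[names(rec) == "control_top"] <- "living_top"
  names(rec)[names(rec) == "tmp"] <- "control_top"
  rev <- difference_series(temp_log(rec, 60), "top")$samples$value
  expect_equal(rev, -fwd)
})

test_that("a missing channel is reported by name", {
  log <- make_temp_log(channels = c("living_top", "living_bottom"))
  err <- expect_error(difference_series(log, "top"),
                      class = "thermocol_missing_channel")
  expect_match(conditionMessage(err), "control_top")
})

test_that("samples exist only where both channels have readings", {
  log <- make_temp_log(days = 1, channels = c("living_top", "living_bottom"))
  log$records$living_top[10:20] <- NA
  log$records$living_bottom[15:25] <- NA
  ds <- difference_series(temp_log(log$records, 60), "tb_int_living")
  expect_equal(nrow(ds$samples), nrow(log$records) - 16)
  expect_equal(ds$n_unmatched, 16L)
})

test_that("common offsets cancel; minuend-only offsets shift exactly", {
  base <- function(ts, ch) 25 + sin(as.numeric(ts) / 4000)
  log <- make_temp_log(days = 1, channels = c("living_top", "living_bottom"),
                       value = base)
  d0 <- difference_series(log, "tb_int_living")$samples$value
  both <- log$records
  both$living_top <- both$living_top + 0.7
  both$living_bottom <- both$living_bottom + 0.7
  d_both <- difference_series(temp_log(both, 60), "tb_int_living")$samples$value
  expect_equal(d_both, d0)
  minuend <- log$records
  minuend$living_top <- minuend$living_top + 0.7
  d_min <- difference_series(temp_log(minuend, 60), "tb_int_living")$samples$value
  expect_equal(d_min, d0 + 0.7)
})

test_that("top/bottom and internal-gradient differences satisfy the identity", {
  set.seed(7)
  log <- make_temp_log(days = 1, value = function(ts, ch) {
    25 + rnorm(length(ts), 0, 0.2)
  })
  top <- difference_series(log, "top")$samples$value
  bott <- difference_series(log, "bottom")$samples$value
  gl <- difference_series(log, "tb_int_living")$samples$value
  gc <- difference_series(log, "tb_int_control")$samples$value
  expect_equal(top - bott, gl - gc)
})

test_that("boxplot statistics summarize per-day phase means", {
  ds <- make_constant_day_series(c(0.5, 0.55, 0.6))
  b <- phase_boxplot_stats(ds, phase = "D2")
  expect_equal(b$median, 0.55)
  expect_equal(b$mean, 0.55)
  expect_equal(b$min, 0.5)
  expect_equal(b$max, 0.6)
  expect_equal(b$q1, 0.525)  # linear interpolation between order statistics
  expect_equal(b$n_days, 3L)

  single <- phase_boxplot_stats(make_constant_day_series(0.42), phase = "N1")
  expect_true(all(unlist(single[c("min", "q1", "median", "q3", "max", "mean")])
                  == 0.42))
  expect_equal(single$sd, 0)
})

test_that("boxplot statistics warn and return empty with zero valid days", {
  ds <- make_constant_day_series(c(0.5, 0.6))
  ds$samples <- ds$samples[1:10, ]  # far below coverage
  expect_warning(b <- phase_boxplot_stats(ds, phase = "D2"), "no valid days")
  expect_equal(nrow(b), 0)
})

test_that("monthly aggregates average per-day phase means over valid days", {
  ds <- make_constant_day_series(c(24, 26))
  s <- summarize_phases(ds)
  m <- monthly_aggregate(s, channel = "top", phase = "D1")
  expect_equal(m$mean, 25)
  expect_equal(m$valid_days, 2L)
  expect_equal(m$month, "2022-04")

  one <- monthly_aggregate(summarize_phases(make_constant_day_series(24.5)),
                           channel = "top", phase = "N2")
  expect_equal(one$mean, 24.5)
  expect_equal(one$sd, 0)
  expect_equal(one$valid_days, 1L)
})

test_that("interrupted days drop out of the monthly aggregate", {
  ds <- make_constant_day_series(c(24, 26, 28))
  # corrupt day 2's D1 interval down to a handful of samples
  lt <- as.POSIXlt(ds$samples$timestamp)
  mins <- lt$hour * 60 + lt$min
  day <- as.Date(format(ds$samples$timestamp, "%Y-%m-%d"))
  cut <- day == as.Date("2022-04-02") & mins >= 480 & mins < 925
  ds$samples <- ds$samples[!cut, ]
  m <- monthly_aggregate(summarize_phases(ds), channel = "top", phase = "D1")
  expect_equal(m$valid_days, 2L)
  expect_equal(m$mean, 26)  # (24 + 28) / 2
  n1 <- monthly_aggregate(summarize_phases(ds), channel = "top", phase = "N1")
  expect_equal(n1$valid_days, 3L)
})
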