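#' Recognized temperature channels
#'
#' Canonical channel identifiers for the instrumented columns: internal
#' top/bottom probes of the living and control columns, the incubator
#' reference, and optional external wall probes paired with each internal
#' probe by shared prefix.
#'
#' @return Character vector of canonical channel names.
#' @export
channel_ids <- function() {
  c("living_top", "living_bottom", "control_top", "control_bottom",
    "incubator",
    "living_top_ext", "living_bottom_ext", "control_top_ext",
    "control_bottom_ext")
}

#' Channel alias table
#'
#' Maps header names found in logger files to canonical channel identifiers.
#' Matching is case-insensitive and ignores surrounding whitespace.
#'
#' @return A tibble with columns `alias` and `channel`.
#' @export
channel_aliases <- function() {
  tibble::tribble(
    ~alias,               ~channel,
    "Living Top",          "living_top",
    "Living Bottom",       "living_bottom",
    "Control Top",         "control_top",
    "Control Bottom",      "control_bottom",
    "Incubator",           "incubator",
    "Living Top Ext",      "living_top_ext",
    "Living Bottom Ext",   "living_bottom_ext",
    "Control Top Ext",     "control_top_ext",
    "Control Bottom Ext",  "control_bottom_ext",
    "T_LT",                "living_top",
    "T_LB",                "living_bottom",
    "T_CT",                "control_top",
    "T_CB",                "control_bottom",
    "T_Inc",               "incubator",
    "T_LT_Ext",            "living_top_ext",
    "T_LB_Ext",            "living_bottom_ext",
    "T_CT_Ext",            "control_top_ext",
    "T_CB_Ext",            "control_bottom_ext")
}

display_channel_names <- function(channels) {
  al <- channel_aliases()
  # first alias per channel is the display form
  vapply(channels, function(ch) al$alias[match(ch, al$channel)], "")
}

resolve_channel <- function(header) {
  al <- channel_aliases()
  key <- tolower(trimws(header))
  hit <- match(key, tolower(al$alias))
  if (is.na(hit)) {
    # canonical ids are accepted verbatim too
    if (key %in% channel_ids()) return(key)
    stop_thermocol(
      sprintf("unknown channel header '%s'; recognized aliases: %s",
              header, paste(unique(al$alias), collapse = ", ")),
      "thermocol_header_error")
  }
  al$channel[hit]
}

#' Multi-channel temperature log
#'
#' Container for timestamped multi-channel temperature observations. The
#' `records` tibble holds one row per timestamp with a `timestamp` column
#' (POSIXct, naive local clock stored as UTC) and one numeric column per
#' channel; per-channel values may be `NA` where a reading was dropped.
#'
#' @param records Tibble with `timestamp` plus channel columns.
#' @param sampling_period Nominal sampling period (seconds).
#' @param n_dropped Count of out-of-plausibility readings dropped at ingest.
#' @param n_skipped_rows Count of unparseable rows skipped at ingest.
#' @return An object of class `temp_log`.
#' @export
temp_log <- function(records, sampling_period = 60, n_dropped = 0L,
                     n_skipped_rows = 0L) {
  stopifnot(is.data.frame(records), "timestamp" %in% names(records))
  records <- tibble::as_tibble(records)
  if (!inherits(records$timestamp, "POSIXct")) {
    stop_thermocol("`records$timestamp` must be POSIXct", "thermocol_config_error")
  }
  channels <- setdiff(names(records), "timestamp")
  if (length(channels) == 0L) {
    stop_thermocol("log has no channel columns", "thermocol_config_error")
  }
  bad <- setdiff(channels, channel_ids())
  if (length(bad) > 0L) {
    stop_thermocol(sprintf("unknown channels: %s", paste(bad, collapse = ", ")),
                   "thermocol_header_error")
  }
  if (nrow(records) > 1L && any(diff(as.numeric(records$timestamp)) <= 0)) {
    stop_thermocol("timestamps must be strictly increasing", "thermocol_config_error")
  }
  check_number(sampling_period, "sampling_period", min = 0, strict_min = TRUE)
  structure(
    list(records = records, channels = channels,
         sampling_period = sampling_period,
         n_dropped = as.integer(n_dropped),
         n_skipped_rows = as.integer(n_skipped_rows)),
    class = "temp_log")
}

#' @export
print.temp_log <- function(x, ...) {
  rng <- if (nrow(x$records)) {
    paste(format(range(x$records$timestamp), "%Y-%m-%d %H:%M"), collapse = " .. ")
  } else "empty"
  cat(sprintf("<temp_log> %d records, %d channels, %gs sampling [%s]\n",
              nrow(x$records), length(x$channels), x$sampling_period, rng))
  gaps <- log_gaps(x)
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  gaps: %d; dropped cells: %d; skipped rows: %d\n",
              nrow(gaps), x$n_dropped, x$n_skipped_rows))
  invisible(x)
}

#' Gap report of a log
#'
#' An uncovered interval is reported wherever consecutive timestamps are
#' more than `3 * sampling_period` apart.
#'
#' @param log A [temp_log()].
#' @return Tibble with columns `start`, `end` (POSIXct) and
#'   `duration` (seconds); zero rows when the log has no gaps.
#' @export
log_gaps <- function(log) {
  stopifnot(inherits(log, "temp_log"))
  ts <- log$records$timestamp
  if (length(ts) < 2L) {
    return(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration = numeric()))
  }
  d <- diff(as.numeric(ts))
  i <- which(d > 3 * log$sampling_period)
  tibble::tibble(start = ts[i], end = ts[i + 1L], duration = d[i])
}

parse_log_timestamp <- function(x, tz = "UTC") {
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  }
  retry <- is.na(out)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], tz = tz, format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Read a semicolon-delimited temperature log
#'
#' Parses the logger's native dialect: one header row naming the timestamp
#' column and the sensor channels (alias table [channel_aliases()]), then
#' semicolon-separated rows of ISO-8601-style local timestamps and
#' temperatures in °C. Readings outside the plausibility window are dropped
#' (set `NA`) and counted; rows whose timestamp cannot be parsed are skipped
#' with a warning and counted.
#'
#' @param path Path to the log file.
#' @param sampling_period Nominal sampling period (seconds), default 60.
#' @param plausibility Length-2 numeric window (°C); readings outside it are
#'   dropped. Default `c(-10, 60)`.
#' @param tz Timezone used to store the naive local timestamps ("UTC" keeps
#'   them free of daylight-saving arithmetic).
#' @return A [temp_log()].
#' @export
read_temp_log <- function(path, sampling_period = 60,
                          plausibility = c(-10, 60), tz = "UTC") {
  if (!file.exists(path)) {
    stop_thermocol(sprintf("log file '%s' does not exist", path),
                   "thermocol_io_error")
  }
  raw <- utils::read.table(path, sep = ";", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           strip.white = TRUE)
  ts_names <- c("timestamp", "time", "datetime", "date time")
  ts_col <- which(tolower(trimws(names(raw))) %in% ts_names)
  if (length(ts_col) != 1L) {
    stop_thermocol(
      "log must have exactly one timestamp column (header 'Timestamp')",
      "thermocol_header_error")
  }
  chan_cols <- setdiff(seq_along(raw), ts_col)
  channels <- vapply(names(raw)[chan_cols], resolve_channel, "")
  if (anyDuplicated(channels)) {
    stop_thermocol("duplicate channel headers in log", "thermocol_header_error")
  }
  ts <- parse_log_timestamp(raw[[ts_col]], tz = tz)
  bad_ts <- is.na(ts)
  n_skipped <- sum(bad_ts)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d row(s) with unparseable timestamps in '%s'",
                    n_skipped, path))
  }
  vals <- lapply(raw[chan_cols], function(col) suppressWarnings(as.numeric(col)))
  rec <- tibble::as_tibble(setNames(vals, channels))
  rec$timestamp <- ts
  rec <- rec[!bad_ts, c("timestamp", channels)]
  # plausibility filter
  n_dropped <- 0L
  for (ch in channels) {
    out <- !is.na(rec[[ch]]) &
      (rec[[ch]] < plausibility[1] | rec[[ch]] > plausibility[2])
    n_dropped <- n_dropped + sum(out)
    rec[[ch]][out] <- NA_real_
  }
  rec <- rec[order(rec$timestamp), ]
  temp_log(rec, sampling_period = sampling_period,
           n_dropped = n_dropped, n_skipped_rows = n_skipped)
}

#' Write a temperature log in the native dialect
#'
#' Semicolon separators, one header row with display channel names, local
#' timestamps formatted `YYYY-mm-dd HH:MM:SS`, temperatures printed to
#' `digits` decimal places (4 by default, enough to represent the 0.0625 °C
#' quantization exactly).
#'
#' @param log A [temp_log()].
#' @param path Output file path.
#' @param digits Decimal places for temperatures.
#' @return `path`, invisibly.
#' @export
write_temp_log <- function(log, path, digits = 4) {
  stopifnot(inherits(log, "temp_log"))
  rec <- log$records
  out <- data.frame(
    Timestamp = format(rec$timestamp, "%Y-%m-%d %H:%M:%S"),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (ch in log$channels) {
    out[[display_channel_names(ch)]] <-
      ifelse(is.na(rec[[ch]]), "", sprintf(paste0("%.", digits, "f"), rec[[ch]]))
  }
  utils::write.table(out, path, sep = ";", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge temperature logs
#'
#' Concatenates logs with identical channel sets, sorts by timestamp, keeps
#' the first record at exact-duplicate timestamps, and leaves gaps to be
#' recomputed from the merged record sequence. Merging is order-insensitive
#' and associative.
#'
#' @param ... [temp_log()] objects, or a single list of them.
#' @return A merged [temp_log()].
#' @export
merge_temp_logs <- function(...) {
  logs <- list(...)
  if (length(logs) == 1L && !inherits(logs[[1]], "temp_log")) logs <- logs[[1]]
  stopifnot(length(logs) >= 1L, all(vapply(logs, inherits, TRUE, "temp_log")))
  ref <- sort(logs[[1]]$channels)
  for (lg in logs[-1]) {
    if (!identical(sort(lg$channels), ref)) {
      stop_thermocol(
        sprintf("channel sets differ: {%s} vs {%s}",
                paste(ref, collapse = ","),
                paste(sort(lg$channels), collapse = ",")),
        "thermocol_merge_error")
    }
  }
  cols <- c("timestamp", logs[[1]]$channels)
  rec <- dplyr::bind_rows(lapply(logs, function(lg) lg$records[cols]))
  rec <- rec[order(rec$timestamp), ]
  rec <- rec[!duplicated(rec$timestamp), ]
  temp_log(rec,
           sampling_period = logs[[1]]$sampling_period,
           n_dropped = sum(vapply(logs, `[[`, 0L, "n_dropped")),
           n_skipped_rows = sum(vapply(logs, `[[`, 0L, "n_skipped_rows")))
}

#' Valid measurement days for a phase
#'
#' A calendar day is valid for a phase when the fraction of expected samples
#' present within that phase's clock interval is at least `min_coverage`.
#' Expected samples are the phase duration divided by the nominal sampling
#' period; a sample counts as present when all requested channels have a
#' non-missing reading.
#'
#' @param log A [temp_log()].
#' @param phase Phase label (e.g. `"D1"`).
#' @param schedule A [phase_schedule()].
#' @param min_coverage Minimum present fraction in (0, 1]; default 0.9.
#' @param channels Channels that must be present; defaults to all channels
#'   in the log.
#' @return A list with `count` and `days` (a `Date` vector).
#' @export
valid_days <- function(log, phase, schedule = phase_schedule(),
                       min_coverage = 0.9, channels = NULL) {
  stopifnot(inherits(log, "temp_log"), inherits(schedule, "phase_schedule"))
  check_number(min_coverage, "min_coverage", min = 0, max = 1, strict_min = TRUE)
  channels <- channels %||% log$channels
  stopifnot(all(channels %in% log$channels))
  rec <- log$records
  if (nrow(rec) == 0L) return(list(count = 0L, days = as.Date(character())))
  iv <- schedule$intervals[schedule$intervals$label == phase, ]
  if (nrow(iv) != 1L) {
    stop_thermocol(sprintf("phase '%s' is not in the schedule", phase),
                   "thermocol_config_error")
  }
  expected <- (iv$end_min - iv$start_min) * 60 / log$sampling_period
  mod <- minute_of_day(rec$timestamp)
  in_phase <- mod >= iv$start_min & mod < iv$end_min
  present <- in_phase & !Reduce(`|`, lapply(rec[channels], is.na))
  all_days <- seq(min(ts_date(rec$timestamp)), max(ts_date(rec$timestamp)),
                  by = "day")
  counts <- table(factor(as.character(ts_date(rec$timestamp[present])),
                         levels = as.character(all_days)))
  ok <- as.integer(counts) >= min_coverage * expected
  days <- all_days[ok]
  list(count = length(days), days = days)
}
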