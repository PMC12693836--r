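#' Diel phase schedule
#'
#' Partition of the 24-h day into analysis phases and excluded transitions.
#' The default schedule follows the incubator light program: sundown
#' transition T1 (00:00-01:00), night quarters N1 (01:00-04:00) and
#' N2 (04:00-07:00), sunrise transition T2 (07:00-08:00), and day quarters
#' D1 (08:00-15:30) and D2 (15:30-24:00). Intervals are half-open
#' `[start, end)`; an end of "00:00" is read as 24:00 of the same day, so D2
#' belongs wholly to its start date. T1 and T2 are excluded from analysis to
#' avoid the light-intensity ramps.
#'
#' @param intervals Data frame with columns `label`, `start`, `end`
#'   ("HH:MM" clock strings); must partition the day exactly.
#' @param excluded Labels treated as excluded transitions.
#' @return An object of class `phase_schedule`.
#' @examples
#' sched <- phase_schedule()
#' phase_durations(sched)
#' @export
phase_schedule <- function(intervals = default_phase_intervals(),
                           excluded = c("T1", "T2")) {
  stopifnot(is.data.frame(intervals),
            all(c("label", "start", "end") %in% names(intervals)))
  start_min <- clock_to_min(intervals$start)
  end_min <- clock_to_min(intervals$end)
  end_min[end_min == 0] <- 1440  # "00:00" as an end means midnight of the same day
  if (any(end_min <= start_min)) {
    stop_thermocol("each phase interval must end after it starts",
                   "thermocol_config_error")
  }
  iv <- tibble::tibble(label = as.character(intervals$label),
                       start_min = start_min, end_min = end_min)
  iv <- iv[order(iv$start_min), ]
  if (anyDuplicated(iv$label)) {
    stop_thermocol("phase labels must be unique", "thermocol_config_error")
  }
  covers <- iv$start_min[1] == 0 && iv$end_min[nrow(iv)] == 1440 &&
    all(iv$end_min[-nrow(iv)] == iv$start_min[-1])
  if (!covers) {
    stop_thermocol("phase intervals must partition the 24-h day exactly",
                   "thermocol_config_error")
  }
  if (!all(excluded %in% iv$label)) {
    stop_thermocol("excluded labels must appear in the schedule",
                   "thermocol_config_error")
  }
  structure(list(intervals = iv, excluded = excluded),
            class = "phase_schedule")
}

#' Default diel phase intervals
#'
#' @return A tibble of the six default intervals.
#' @export
default_phase_intervals <- function() {
  tibble::tribble(
    ~label, ~start,  ~end,
    "T1",   "00:00", "01:00",
    "N1",   "01:00", "04:00",
    "N2",   "04:00", "07:00",
    "T2",   "07:00", "08:00",
    "D1",   "08:00", "15:30",
    "D2",   "15:30", "00:00")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("<phase_schedule>\n")
  iv <- x$intervals
  for (i in seq_len(nrow(iv))) {
    cat(sprintf("  %-3s %s-%s%s\n", iv$label[i], min_to_clock(iv$start_min[i]),
                min_to_clock(iv$end_min[i] %% 1440),
                if (iv$label[i] %in% x$excluded) "  (excluded transition)" else ""))
  }
  invisible(x)
}

#' Phase durations in minutes
#'
#' @param schedule A [phase_schedule()].
#' @return Named numeric vector of interval durations (minutes).
#' @export
phase_durations <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  iv <- schedule$intervals
  setNames(iv$end_min - iv$start_min, iv$label)
}

#' Analysis phases of a schedule
#'
#' @param schedule A [phase_schedule()].
#' @return Labels of the non-excluded phases, in clock order.
#' @export
analysis_phases <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  setdiff(schedule$intervals$label, schedule$excluded)
}

#' Label timestamps with their diel phase
#'
#' Total over the day: every timestamp maps to exactly one interval by
#' half-open membership, including the excluded transitions (which carry
#' their own labels, `T1`/`T2` by default).
#'
#' @param ts POSIXct timestamps.
#' @param schedule A [phase_schedule()].
#' @return Character vector of phase labels.
#' @examples
#' sched <- phase_schedule()
#' label_timestamp(as.POSIXct("2022-04-03 09:00:00", tz = "UTC"), sched)
#' @export
label_timestamp <- function(ts, schedule = phase_schedule()) {
  stopifnot(inherits(schedule, "phase_schedule"))
  iv <- schedule$intervals
  mod <- minute_of_day(ts)
  idx <- findInterval(mod, iv$start_min)
  idx[mod >= 1440] <- nrow(iv)  # guard against rounding at midnight
  iv$label[idx]
}

#' Is a phase label an excluded transition?
#'
#' @param label Phase labels.
#' @param schedule A [phase_schedule()].
#' @return Logical vector.
#' @export
is_excluded_phase <- function(label, schedule = phase_schedule()) {
  label %in% schedule$excluded
}

#' Calendar date owning a phase observation
#'
#' All default phase intervals begin and end within one calendar day (D2
#' ends at 24:00), so the phase-day of a timestamp is simply the calendar
#' date containing its interval's start. Excluded timestamps have no
#' phase-day and raise an error.
#'
#' @param ts POSIXct timestamps.
#' @param schedule A [phase_schedule()].
#' @return A `Date` vector.
#' @export
phase_day <- function(ts, schedule = phase_schedule()) {
  lab <- label_timestamp(ts, schedule)
  if (any(is_excluded_phase(lab, schedule))) {
    stop_thermocol("excluded transition timestamps have no phase-day",
                   "thermocol_domain_error")
  }
  ts_date(ts)
}

#' Per-day, per-phase channel summaries
#'
#' Splits a log by calendar day and analysis phase and reports, for every
#' (day, phase, channel) with at least one sample, the arithmetic mean, the
#' sample standard deviation (n-1 denominator; 0 when n = 1), and the sample
#' count. Excluded transitions are omitted.
#'
#' @param log A [temp_log()] or a [difference_series()].
#' @param schedule A [phase_schedule()].
#' @return A tibble with columns `day`, `phase`, `channel`, `mean`, `sd`, `n`.
#' @export
summarize_phases <- function(log, schedule = phase_schedule()) {
  UseMethod("summarize_phases")
}

#' @export
summarize_phases.temp_log <- function(log, schedule = phase_schedule()) {
  stopifnot(inherits(schedule, "phase_schedule"))
  rec <- log$records
  if (nrow(rec) == 0L) {
    stop_thermocol("log is empty", "thermocol_domain_error")
  }
  long <- tidyr::pivot_longer(rec, cols = dplyr::all_of(log$channels),
                              names_to = "channel", values_to = "value")
  long <- long[!is.na(long$value), ]
  long$phase <- label_timestamp(long$timestamp, schedule)
  long <- long[!is_excluded_phase(long$phase, schedule), ]
  long$day <- ts_date(long$timestamp)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$day, .data$phase, .data$channel),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
    n = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$day, .data$phase, .data$channel)
}

#' @export
summarize_phases.difference_series <- function(log, schedule = phase_schedule()) {
  stopifnot(inherits(schedule, "phase_schedule"))
  s <- log$samples
  if (nrow(s) == 0L) {
    stop_thermocol("difference series is empty", "thermocol_domain_error")
  }
  s$phase <- label_timestamp(s$timestamp, schedule)
  s <- s[!is_excluded_phase(s$phase, schedule), ]
  s$day <- ts_date(s$timestamp)
  out <- dplyr::summarise(
    dplyr::group_by(s, .data$day, .data$phase),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
    n = dplyr::n(), .groups = "drop")
  out$channel <- log$kind
  dplyr::arrange(out[, c("day", "phase", "channel", "mean", "sd", "n")],
                 .data$day, .data$phase)
}
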