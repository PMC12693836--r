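#' Insulation event
#'
#' One wrapping of both columns in insulating material while logging
#' continued, described by its start and end instants and the wrap type.
#'
#' @param start,end POSIXct instants; `start` must precede `end`.
#' @param wrap Wrap label, e.g. `"foil"` or `"foil+PE"`.
#' @param notes Free-text notes.
#' @param conductance_scale Factor in (0, 1] applied to the columns'
#'   external (lateral) conductances while the event is active; used by the
#'   simulator. The base-loss path stays unscaled (the column base cannot be
#'   wrapped).
#' @return An object of class `insulation_event`.
#' @export
insulation_event <- function(start, end, wrap = "foil", notes = "",
                             conductance_scale = 0.3) {
  stopifnot(inherits(start, "POSIXct"), inherits(end, "POSIXct"))
  if (!(start < end)) {
    stop_thermocol("insulation event must start before it ends",
                   "thermocol_config_error")
  }
  check_number(conductance_scale, "conductance_scale", min = 0, max = 1,
               strict_min = TRUE)
  structure(list(start = start, end = end, wrap = wrap, notes = notes,
                 conductance_scale = conductance_scale),
            class = "insulation_event")
}

#' @export
print.insulation_event <- function(x, ...) {
  cat(sprintf("<insulation_event> %s: %s .. %s (K_ext x %g)\n", x$wrap,
              format(x$start, "%Y-%m-%d %H:%M"),
              format(x$end, "%Y-%m-%d %H:%M"), x$conductance_scale))
  invisible(x)
}

# Which phase-days of a daily-means table overlap the event for a phase?
event_overlaps_day <- function(days, iv, event) {
  day0 <- as.POSIXct(paste(format(days), "00:00:00"), tz = "UTC")
  p_start <- day0 + iv$start_min * 60
  p_end <- day0 + iv$end_min * 60
  p_start < event$end & p_end > event$start
}

#' Temperature retention statistics for an insulation event
#'
#' For each analysis phase, computes the temperature retention
#' `delta_delta` — the highest per-day phase mean of the difference series
#' during the insulation minus the mean over the preceding `baseline_days`
#' valid phase-days — and the steady-state retention `delta_delta_steady` —
#' the mean over the first `post_days` valid phase-days after the event
#' minus the same baseline. Days whose phase interval overlaps the event at
#' all count as "during"; their means use only the overlapped portion of
#' the interval, and baseline/post windows begin at the nearest fully
#' uncovered day, skipping invalid (interrupted) days rather than shrinking.
#'
#' @param series A [difference_series()] (typically kind `"top"` or
#'   `"bottom"`).
#' @param event An [insulation_event()].
#' @param schedule A [phase_schedule()].
#' @param baseline_days,post_days Number of valid phase-days in the pre- and
#'   post-event windows (default 3 each).
#' @param sampling_period,min_coverage Valid-day rule (see
#'   [daily_phase_means()]).
#' @param phases Phases to evaluate; defaults to all analysis phases.
#' @return A tibble of class `retention_result` with one row per phase:
#'   `region`, `phase`, `delta_delta`, `delta_delta_steady`,
#'   `baseline_mean`, `during_max_day_mean`, `post_mean`, `baseline_days`,
#'   `post_days`.
#' @export
retention_stats <- function(series, event, schedule = phase_schedule(),
                            baseline_days = 3, post_days = 3,
                            sampling_period = 60, min_coverage = 0.9,
                            phases = analysis_phases(schedule)) {
  stopifnot(inherits(series, "difference_series"),
            inherits(event, "insulation_event"))
  region <- switch(series$kind, top = "top", bottom = "bottom", NA_character_)
  samples <- series$samples
  samples$phase <- label_timestamp(samples$timestamp, schedule)
  samples$day <- ts_date(samples$timestamp)
  daily <- daily_phase_means(series, schedule, sampling_period, min_coverage)

  rows <- lapply(phases, function(ph) {
    iv <- schedule$intervals[schedule$intervals$label == ph, ]
    d <- daily[daily$phase == ph, ]
    if (nrow(d) == 0L) {
      stop_thermocol(sprintf("no data for phase '%s'", ph),
                     "thermocol_insufficient_coverage")
    }
    during <- event_overlaps_day(d$day, iv, event)
    if (!any(during)) {
      stop_thermocol(
        sprintf("event does not overlap any '%s' phase-day in the series", ph),
        "thermocol_insufficient_coverage")
    }
    first_during <- min(d$day[during])
    last_during <- max(d$day[during])

    pre <- d[d$day < first_during & d$valid, ]
    if (nrow(pre) < baseline_days) {
      stop_thermocol(
        sprintf("phase '%s': only %d valid day(s) before the event; %d required",
                ph, nrow(pre), baseline_days),
        "thermocol_insufficient_coverage")
    }
    pre <- tail(pre[order(pre$day), ], baseline_days)

    post <- d[d$day > last_during & d$valid, ]
    if (nrow(post) < post_days) {
      stop_thermocol(
        sprintf("phase '%s': only %d valid day(s) after the event; %d required",
                ph, nrow(post), post_days),
        "thermocol_insufficient_coverage")
    }
    post <- head(post[order(post$day), ], post_days)

    # during-day means restricted to the overlapped portion of the phase
    during_days <- d$day[during]
    during_means <- vapply(during_days, function(dd) {
      s <- samples[samples$day == dd & samples$phase == ph &
                     samples$timestamp >= event$start &
                     samples$timestamp <= event$end, , drop = FALSE]
      if (nrow(s) == 0L) NA_real_ else mean(s$value)
    }, numeric(1))
    during_means <- during_means[!is.na(during_means)]
    if (length(during_means) == 0L) {
      stop_thermocol(
        sprintf("phase '%s': no samples inside the event window", ph),
        "thermocol_insufficient_coverage")
    }

    baseline_mean <- mean(pre$mean)
    during_max <- max(during_means)
    post_mean <- mean(post$mean)
    tibble::tibble(
      region = region, phase = ph,
      delta_delta = during_max - baseline_mean,
      delta_delta_steady = post_mean - baseline_mean,
      baseline_mean = baseline_mean,
      during_max_day_mean = during_max,
      post_mean = post_mean,
      baseline_days = nrow(pre), post_days = nrow(post))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("retention_result", class(out))
  out
}

#' Flag retention statistics against the sensor precision
#'
#' Compares the absolute value of each statistic to the sensor's
#' quantization step: values strictly above the step are physically
#' resolvable, values strictly below are not, and values exactly at the
#' step are reported distinctly.
#'
#' @param x Numeric values (°C), or a `retention_result` tibble.
#' @param sensor A [sensor_spec()].
#' @return For numeric input, a character vector of `"above"`, `"below"`,
#'   `"at-threshold"`. For a `retention_result`, the tibble with
#'   `delta_delta_flag` and `delta_delta_steady_flag` columns appended.
#' @examples
#' precision_flag(c(0.25, 0.01, 0.0625), sensor_spec())
#' @export
precision_flag <- function(x, sensor = sensor_spec()) {
  stopifnot(inherits(sensor, "sensor_spec"))
  if (inherits(x, "retention_result")) {
    x$delta_delta_flag <- precision_flag(x$delta_delta, sensor)
    x$delta_delta_steady_flag <- precision_flag(x$delta_delta_steady, sensor)
    return(x)
  }
  res <- sensor$resolution
  out <- ifelse(abs(x) > res, "above",
                ifelse(abs(x) < res, "below", "at-threshold"))
  as.character(out)
}
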