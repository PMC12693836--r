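#' Difference-series kinds
#'
#' The channel pairs behind each difference series: vertical top-minus-bottom
#' gradients within each column (internal probes, or external wall
#' references), and living-minus-control differences at the top and bottom
#' positions.
#'
#' @return A tibble with columns `kind`, `minuend`, `subtrahend`.
#' @export
difference_kinds <- function() {
  tibble::tribble(
    ~kind,             ~minuend,          ~subtrahend,
    "tb_int_living",   "living_top",      "living_bottom",
    "tb_int_control",  "control_top",     "control_bottom",
    "tb_ext_living",   "living_top_ext",  "living_bottom_ext",
    "tb_ext_control",  "control_top_ext", "control_bottom_ext",
    "top",             "living_top",      "control_top",
    "bottom",          "living_bottom",   "control_bottom")
}

#' Pointwise difference series between two channels
#'
#' Computes minuend minus subtrahend at shared timestamps only: a sample is
#' emitted where both channels have a reading. Timestamps are snapped to the
#' nominal sampling grid (rounded to the nearest sampling period) before
#' pairing, which guards against logger jitter; snapped duplicates keep the
#' first reading.
#'
#' @param log A [temp_log()].
#' @param kind One of the kinds in [difference_kinds()].
#' @return An object of class `difference_series`: a list with `kind`,
#'   `minuend`, `subtrahend`, and `samples` (tibble of `timestamp`, `value`).
#' @examples
#' \dontrun{
#' ds <- difference_series(sim$log, "tb_int_living")
#' }
#' @export
difference_series <- function(log, kind) {
  stopifnot(inherits(log, "temp_log"))
  kinds <- difference_kinds()
  row <- kinds[kinds$kind == kind, ]
  if (nrow(row) != 1L) {
    stop_thermocol(sprintf("unknown difference kind '%s'; use one of: %s",
                           kind, paste(kinds$kind, collapse = ", ")),
                   "thermocol_config_error")
  }
  for (ch in c(row$minuend, row$subtrahend)) {
    if (!ch %in% log$channels) {
      stop_thermocol(sprintf("channel '%s' required for kind '%s' is missing",
                             ch, kind),
                     "thermocol_missing_channel")
    }
  }
  rec <- log$records
  snapped <- round(as.numeric(rec$timestamp) / log$sampling_period) *
    log$sampling_period
  keep <- !duplicated(snapped)
  rec <- rec[keep, ]
  ts <- as.POSIXct(snapped[keep], origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(rec[[row$minuend]]) & !is.na(rec[[row$subtrahend]])
  structure(
    list(kind = kind, minuend = row$minuend, subtrahend = row$subtrahend,
         samples = tibble::tibble(
           timestamp = ts[ok],
           value = rec[[row$minuend]][ok] - rec[[row$subtrahend]][ok]),
         n_unmatched = sum(!ok)),
    class = "difference_series")
}

#' @export
print.difference_series <- function(x, ...) {
  cat(sprintf("<difference_series> %s = %s - %s: %d samples\n",
              x$kind, x$minuend, x$subtrahend, nrow(x$samples)))
  invisible(x)
}

#' Per-day phase means of a difference series
#'
#' The first level of the hierarchical aggregation: raw samples are averaged
#' within each (day, phase) cell. A `valid` flag marks days meeting the
#' coverage rule for that phase.
#'
#' @param series A [difference_series()].
#' @param schedule A [phase_schedule()].
#' @param sampling_period Nominal sampling period (seconds) used for the
#'   expected-sample count.
#' @param min_coverage Minimum present fraction for a day to be valid.
#' @return Tibble with `day`, `phase`, `mean`, `sd`, `n`, `valid`.
#' @export
daily_phase_means <- function(series, schedule = phase_schedule(),
                              sampling_period = 60, min_coverage = 0.9) {
  stopifnot(inherits(series, "difference_series"))
  out <- summarize_phases(series, schedule)
  dur <- phase_durations(schedule)
  expected <- dur[out$phase] * 60 / sampling_period
  out$valid <- out$n >= min_coverage * expected
  out[, c("day", "phase", "mean", "sd", "n", "valid")]
}

#' Boxplot statistics of per-day phase means
#'
#' Five-number summary (minimum, lower quartile, median, upper quartile,
#' maximum; quartiles by linear interpolation between order statistics),
#' mean, and standard deviation of the per-day phase means of a difference
#' series — the quantities drawn as one box in the phase-gradient figures.
#' Aggregation is hierarchical: raw samples are first averaged per valid
#' day, then summarized across days.
#'
#' @param series A [difference_series()].
#' @param schedule A [phase_schedule()].
#' @param phase Phase label.
#' @param sampling_period,min_coverage Valid-day rule (see
#'   [daily_phase_means()]).
#' @return A tibble with one row: `phase`, `min`, `q1`, `median`, `q3`,
#'   `max`, `mean`, `sd`, `n_days`; zero rows (with a warning) when no day
#'   is valid.
#' @export
phase_boxplot_stats <- function(series, schedule = phase_schedule(), phase,
                                sampling_period = 60, min_coverage = 0.9) {
  daily <- daily_phase_means(series, schedule, sampling_period, min_coverage)
  m <- daily$mean[daily$phase == phase & daily$valid]
  if (length(m) == 0L) {
    warning(sprintf("no valid days for phase '%s'", phase))
    return(tibble::tibble(phase = character(), min = numeric(), q1 = numeric(),
                          median = numeric(), q3 = numeric(), max = numeric(),
                          mean = numeric(), sd = numeric(), n_days = integer()))
  }
  q <- stats::quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    phase = phase, min = min(m), q1 = q[1], median = q[2], q3 = q[3],
    max = max(m), mean = mean(m),
    sd = if (length(m) > 1L) stats::sd(m) else 0,
    n_days = length(m))
}

#' Monthly phase aggregates
#'
#' Second level of the hierarchical aggregation: per-day phase means (from
#' [summarize_phases()]) are averaged within each calendar month, per phase
#' and channel (or difference kind), over valid days only. The number of
#' valid days enters the output so months with unequal coverage remain
#' comparable.
#'
#' @param summaries A per-day summary tibble from [summarize_phases()].
#' @param channel Channel or difference-kind name to aggregate.
#' @param phase Phase label.
#' @param schedule A [phase_schedule()].
#' @param sampling_period Nominal sampling period (seconds).
#' @param min_coverage Valid-day coverage threshold.
#' @return Tibble with `month` ("YYYY-MM"), `phase`, `channel`, `mean`,
#'   `sd`, `valid_days`; empty months are absent.
#' @export
monthly_aggregate <- function(summaries, channel, phase,
                              schedule = phase_schedule(),
                              sampling_period = 60, min_coverage = 0.9) {
  stopifnot(is.data.frame(summaries),
            all(c("day", "phase", "channel", "mean", "n") %in% names(summaries)))
  dur <- phase_durations(schedule)
  sub <- summaries[summaries$channel == channel & summaries$phase == phase, ]
  expected <- dur[[phase]] * 60 / sampling_period
  sub <- sub[sub$n >= min_coverage * expected, ]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(month = character(), phase = character(),
                          channel = character(), mean = numeric(),
                          sd = numeric(), valid_days = integer()))
  }
  sub$month <- format(sub$day, "%Y-%m")
  ph <- phase
  chan <- channel
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$month),
    phase = ph, channel = chan,
    mean = mean(.data$mean),
    sd = if (dplyr::n() > 1L) stats::sd(.data$mean) else 0,
    valid_days = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$month)
}
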