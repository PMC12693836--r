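# Shared fixtures and independent oracles for the test suite.

# Build a synthetic temp_log covering `days` full days at `sampling` seconds.
# `value` may be a scalar, a named per-channel vector, or a function
# (timestamp, channel) -> numeric.
make_temp_log <- function(days = 3,
                          channels = c("living_top", "living_bottom",
                                       "control_top", "control_bottom"),
                          value = 25, start = "2022-04-01",
                          sampling = 60) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  ts <- t0 + seq(0, days * 86400 - sampling, by = sampling)
  rec <- tibble::tibble(timestamp = ts)
  for (ch in channels) {
    rec[[ch]] <- if (is.function(value)) {
      value(ts, ch)
    } else if (!is.null(names(value))) {
      rep(value[[ch]], length(ts))
    } else {
      rep(value, length(ts))
    }
  }
  temp_log(rec, sampling_period = sampling)
}

# Construct a difference_series directly from per-day constant values: each
# named day gets that constant at every sampling instant of every phase.
make_constant_day_series <- function(day_values, kind = "top",
                                     start = "2022-04-01", sampling = 60) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  days <- seq_along(day_values) - 1
  ts <- as.POSIXct(unlist(lapply(days, function(d) {
    t0 + d * 86400 + seq(0, 86400 - sampling, by = sampling)
  })), origin = "1970-01-01", tz = "UTC")
  vals <- rep(day_values, each = 86400 / sampling)
  pair <- difference_kinds()
  pair <- pair[pair$kind == kind, ]
  structure(
    list(kind = kind, minuend = pair$minuend, subtrahend = pair$subtrahend,
         samples = tibble::tibble(timestamp = ts, value = vals),
         n_unmatched = 0L),
    class = "difference_series")
}

# Brute-force exact two-sided Mann-Whitney p-value by enumerating every
# assignment of the pooled observations to the first sample. Valid for
# untied data and small n; independent of the package implementation.
mwu_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
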