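#' @importFrom stats sd median quantile setNames wilcox.test approx
#' @importFrom utils head tail
#' @importFrom dplyr .data
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_thermocol <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "thermocol_error")))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_thermocol(sprintf("`%s` must be a single finite number", name),
                   "thermocol_domain_error")
  }
  if (x < min || x > max || (strict_min && x <= min)) {
    stop_thermocol(
      sprintf("`%s` = %g is outside its allowed range [%g, %g]%s",
              name, x, min, max, if (strict_min) " (exclusive lower bound)" else ""),
      "thermocol_domain_error")
  }
  invisible(x)
}

# Round a value to the nearest multiple of `step` (sensor quantization).
round_to_step <- function(x, step) {
  round(x / step) * step
}

# Minutes since local midnight, fractional seconds allowed.
minute_of_day <- function(ts) {
  lt <- as.POSIXlt(ts)
  lt$hour * 60 + lt$min + lt$sec / 60
}

# Calendar date of a timestamp, respecting its own timezone.
ts_date <- function(ts) {
  as.Date(format(ts, "%Y-%m-%d"))
}

# Parse "HH:MM" clock strings to minutes since midnight; "24:00" allowed.
clock_to_min <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) {
      stop_thermocol(sprintf("clock time '%s' is not HH:MM", paste(p, collapse = ":")),
                     "thermocol_config_error")
    }
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

min_to_clock <- function(m) {
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
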