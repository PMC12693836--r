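#' Diurnal incubator forcing
#'
#' The incubator air temperature is modeled as a first-order response to the
#' lamp program — temperature tracks `base_temp + amplitude * light
#' fraction` with time constant `response_tau` — plus white noise, clipped
#' to the incubator's operating band. Optional short disturbance spikes
#' (e.g. laboratory lights switching) affect only the external reference
#' channels, not the columns.
#'
#' @param base_temp Dark-phase asymptotic temperature (°C).
#' @param amplitude Temperature swing at full illumination (°C).
#' @param illumination An [illumination_spec()] supplying the lamp program.
#' @param response_tau First-order response time constant (s).
#' @param noise_sd White-noise standard deviation on the trace (°C).
#' @param band Operating band the trace is clipped to (°C).
#' @param disturbance `NULL`, or a list with `amplitude` (°C),
#'   `rate_per_day`, and `duration_min` describing random spikes added to
#'   external channels only.
#' @return An object of class `incubator_forcing`.
#' @export
incubator_forcing <- function(base_temp = 22.2, amplitude = 7.5,
                              illumination = illumination_spec(),
                              response_tau = 1800, noise_sd = 0.05,
                              band = c(22, 30), disturbance = NULL) {
  check_number(base_temp, "base_temp")
  check_number(amplitude, "amplitude", min = 0)
  check_number(response_tau, "response_tau", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  stopifnot(inherits(illumination, "illumination_spec"),
            length(band) == 2L, band[1] < band[2])
  structure(list(base_temp = base_temp, amplitude = amplitude,
                 illumination = illumination, response_tau = response_tau,
                 noise_sd = noise_sd, band = band, disturbance = disturbance),
            class = "incubator_forcing")
}

#' Two-node lumped-capacitance column model
#'
#' Each column is a two-node thermal network (top and bottom sediment
#' regions, matching the two embedded probes). Each node has a heat
#' capacity, an external conductive coupling to the incubator air, and the
#' two nodes are coupled internally; the bottom node additionally loses heat
#' through the column base via `base_loss`, a path insulation cannot cover.
#' Node sources model microbial heat: the top-node source may scale with the
#' lamp intensity fraction (phototrophic/aerobic activity), the bottom
#' source is typically a small constant.
#'
#' @param heat_capacity Named numeric `c(top=, bottom=)`, J °C⁻¹ per node
#'   (node sediment mass times specific heat).
#' @param conduct_ext Named numeric `c(top=, bottom=)`, node-incubator
#'   conductance (W °C⁻¹); scaled down during insulation events.
#' @param conduct_int Top-bottom conductance (W °C⁻¹).
#' @param base_loss Extra bottom-incubator conductance through the
#'   uninsulatable base (W °C⁻¹).
#' @param source_top,source_bottom Node heat sources (W); zero for a
#'   sterilized control column.
#' @param source_top_light_modulated,source_bottom_light_modulated Whether
#'   each source scales with the lamp intensity fraction.
#' @return An object of class `column_thermal_model`.
#' @export
column_thermal_model <- function(heat_capacity = c(top = 512, bottom = 512),
                                 conduct_ext = c(top = 0.15, bottom = 0.15),
                                 conduct_int = 0.1, base_loss = 0.05,
                                 source_top = 0, source_bottom = 0,
                                 source_top_light_modulated = TRUE,
                                 source_bottom_light_modulated = FALSE) {
  stopifnot(length(heat_capacity) == 2L, length(conduct_ext) == 2L)
  heat_capacity <- setNames(as.numeric(heat_capacity), c("top", "bottom"))
  conduct_ext <- setNames(as.numeric(conduct_ext), c("top", "bottom"))
  if (any(heat_capacity <= 0)) {
    stop_thermocol("node heat capacities must be positive", "thermocol_config_error")
  }
  if (any(c(conduct_ext, conduct_int, base_loss) < 0)) {
    stop_thermocol("conductances must be non-negative", "thermocol_config_error")
  }
  check_number(source_top, "source_top", min = 0)
  check_number(source_bottom, "source_bottom", min = 0)
  structure(list(heat_capacity = heat_capacity, conduct_ext = conduct_ext,
                 conduct_int = conduct_int, base_loss = base_loss,
                 source_top = source_top, source_bottom = source_bottom,
                 source_top_light_modulated = source_top_light_modulated,
                 source_bottom_light_modulated = source_bottom_light_modulated),
            class = "column_thermal_model")
}

#' Sensor observation model
#'
#' Each logged channel is the node (or incubator) temperature plus a fixed
#' per-channel offset plus Gaussian noise, quantized to the sensor
#' resolution. The incubator reference channel uses a separate
#' higher-resolution device and is not quantized. Logging gaps ("technical
#' interruptions") remove whole records.
#'
#' @param offsets Named numeric of per-channel fixed offsets (°C); missing
#'   channels default to 0. Offsets must respect the accuracy bound.
#' @param noise_sd Per-reading Gaussian noise (°C).
#' @param sensor A [sensor_spec()] giving resolution and accuracy bound.
#' @param sampling_period Logging cadence (s).
#' @param dropout `NULL`, a list of `c(start, end)` POSIXct pairs, or a
#'   number of random gaps per day (each 15-60 min).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(offsets = NULL, noise_sd = 0.05,
                         sensor = sensor_spec(), sampling_period = 60,
                         dropout = NULL) {
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(sampling_period, "sampling_period", min = 0, strict_min = TRUE)
  stopifnot(inherits(sensor, "sensor_spec"))
  if (!is.null(offsets)) {
    stopifnot(!is.null(names(offsets)), all(names(offsets) %in% channel_ids()))
    if (any(abs(offsets) > sensor$accuracy)) {
      stop_thermocol("per-channel offsets must lie within the accuracy bound",
                     "thermocol_config_error")
    }
  }
  structure(list(offsets = offsets, noise_sd = noise_sd, sensor = sensor,
                 sampling_period = sampling_period, dropout = dropout),
            class = "sensor_model")
}

#' Full simulation configuration
#'
#' Bundles forcing, the living and control column models, the sensor model,
#' insulation events, and the seed that fixes all randomness.
#'
#' @param duration_days Simulated duration (days).
#' @param start Start instant (POSIXct, midnight-aligned recommended).
#' @param forcing An [incubator_forcing()].
#' @param living,control [column_thermal_model()]s; the control must have
#'   zero sources.
#' @param sensors A [sensor_model()].
#' @param insulation List of [insulation_event()]s (non-overlapping).
#' @param include_external Emit the four external wall-reference channels.
#' @param step Integration step (s); must divide the sampling period and
#'   satisfy the explicit-scheme stability bound.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `column_sim_config`.
#' @export
column_sim_config <- function(duration_days = 7,
                              start = as.POSIXct("2022-04-01 00:00:00", tz = "UTC"),
                              forcing = incubator_forcing(),
                              living = column_thermal_model(source_top = 0.08,
                                                            source_bottom = 0.01),
                              control = column_thermal_model(),
                              sensors = sensor_model(),
                              insulation = list(),
                              include_external = TRUE,
                              step = 60, seed = 1L) {
  check_number(duration_days, "duration_days", min = 0, strict_min = TRUE)
  stopifnot(inherits(start, "POSIXct"), inherits(forcing, "incubator_forcing"),
            inherits(living, "column_thermal_model"),
            inherits(control, "column_thermal_model"),
            inherits(sensors, "sensor_model"))
  if (control$source_top != 0 || control$source_bottom != 0) {
    stop_thermocol("the control column must have zero heat sources",
                   "thermocol_config_error")
  }
  stopifnot(all(vapply(insulation, inherits, TRUE, "insulation_event")))
  if (sensors$sampling_period %% step != 0) {
    stop_thermocol("`step` must divide the sampling period",
                   "thermocol_config_error")
  }
  # explicit-scheme stability: step at most a tenth of the fastest time constant
  tau_min <- min(vapply(list(living, control), function(m) {
    k_tot <- c(m$conduct_ext["top"] + m$conduct_int,
               m$conduct_ext["bottom"] + m$conduct_int + m$base_loss)
    suppressWarnings(min(m$heat_capacity / pmax(k_tot, 1e-300)))
  }, numeric(1)))
  if (step > 0.1 * tau_min) {
    stop_thermocol(
      sprintf(paste0("integration step %gs violates the stability bound ",
                     "(0.1 x smallest time constant = %.1fs); use a smaller step"),
              step, 0.1 * tau_min),
      "thermocol_stability_error")
  }
  structure(list(duration_days = duration_days, start = start,
                 forcing = forcing, living = living, control = control,
                 sensors = sensors, insulation = insulation,
                 include_external = include_external,
                 step = step, seed = as.integer(seed)),
            class = "column_sim_config")
}

with_seed_local <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Simulate two instrumented columns
#'
#' Integrates the two-node lumped-capacitance network of each column under
#' the diurnal incubator forcing with a fixed-step explicit (Euler) scheme,
#' applies insulation events by scaling the external conductances (never the
#' base-loss path), passes node temperatures through the sensor model
#' (offset, Gaussian noise, quantization), and emits a [temp_log()] in the
#' native dialect alongside unquantized ground truth.
#'
#' @param config A [column_sim_config()].
#' @return An object of class `column_simulation`: a list with `log` (a
#'   [temp_log()]), `truth` (tibble of unquantized node and incubator
#'   temperatures, instantaneous source powers, and net node fluxes at each
#'   sampling instant), and `config`.
#' @examples
#' sim <- simulate_columns(scenario_default(days = 2))
#' sim$log
#' @export
simulate_columns <- function(config) {
  stopifnot(inherits(config, "column_sim_config"))
  with_seed_local(config$seed, function() simulate_columns_impl(config))
}

simulate_columns_impl <- function(config) {
  step <- config$step
  n_steps <- round(config$duration_days * 86400 / step)
  k <- seq_len(n_steps + 1L)
  t_sec <- (k - 1L) * step
  start_mod <- minute_of_day(config$start)
  mod <- (start_mod + t_sec / 60) %% 1440

  frc <- config$forcing
  frac <- light_fraction(frc$illumination, mod)
  target <- frc$base_temp + frc$amplitude * frac

  # first-order filtered incubator trace + white noise, clipped to the band
  alpha <- step / frc$response_tau
  t_inc_true <- numeric(n_steps + 1L)
  t_inc_true[1] <- target[1]
  for (i in seq_len(n_steps)) {
    t_inc_true[i + 1] <- t_inc_true[i] + alpha * (target[i] - t_inc_true[i])
  }
  noise <- if (frc$noise_sd > 0) stats::rnorm(n_steps + 1L, 0, frc$noise_sd) else 0
  t_inc <- pmin(pmax(t_inc_true + noise, frc$band[1]), frc$band[2])

  # insulation scale factor per step (events wrap both columns)
  scale <- rep(1, n_steps + 1L)
  times <- config$start + t_sec
  for (ev in config$insulation) {
    on <- times >= ev$start & times < ev$end
    scale[on] <- scale[on] * ev$conductance_scale
  }

  integrate_column <- function(m) {
    Tt <- numeric(n_steps + 1L); Tb <- numeric(n_steps + 1L)
    ft <- numeric(n_steps + 1L); fb <- numeric(n_steps + 1L)
    Pt <- m$source_top * (if (m$source_top_light_modulated) frac else 1)
    Pb <- m$source_bottom * (if (m$source_bottom_light_modulated) frac else 1)
    Pt <- rep_len(Pt, n_steps + 1L); Pb <- rep_len(Pb, n_steps + 1L)
    Tt[1] <- target[1]; Tb[1] <- target[1]
    ket <- m$conduct_ext[["top"]]; keb <- m$conduct_ext[["bottom"]]
    kint <- m$conduct_int; kbase <- m$base_loss
    Ct <- m$heat_capacity[["top"]]; Cb <- m$heat_capacity[["bottom"]]
    for (i in k) {
      ft[i] <- kint * (Tb[i] - Tt[i]) + scale[i] * ket * (t_inc[i] - Tt[i]) + Pt[i]
      fb[i] <- kint * (Tt[i] - Tb[i]) + scale[i] * keb * (t_inc[i] - Tb[i]) +
        kbase * (t_inc[i] - Tb[i]) + Pb[i]
      if (i <= n_steps) {
        Tt[i + 1] <- Tt[i] + step * ft[i] / Ct
        Tb[i + 1] <- Tb[i] + step * fb[i] / Cb
      }
    }
    list(top = Tt, bottom = Tb, flux_top = ft, flux_bottom = fb,
         p_top = Pt, p_bottom = Pb)
  }
  liv <- integrate_column(config$living)
  ctl <- integrate_column(config$control)

  # observation instants
  every <- config$sensors$sampling_period / step
  obs <- which((k - 1L) %% every == 0)
  ts <- times[obs]

  sn <- config$sensors
  res <- sn$sensor$resolution
  offset_of <- function(ch) {
    if (!is.null(sn$offsets) && ch %in% names(sn$offsets)) sn$offsets[[ch]] else 0
  }
  observe <- function(true_vals, ch, quantize = TRUE) {
    v <- true_vals + offset_of(ch) +
      (if (sn$noise_sd > 0) stats::rnorm(length(true_vals), 0, sn$noise_sd) else 0)
    if (quantize) round_to_step(v, res) else v
  }

  rec <- tibble::tibble(
    timestamp = ts,
    living_top = observe(liv$top[obs], "living_top"),
    living_bottom = observe(liv$bottom[obs], "living_bottom"),
    control_top = observe(ctl$top[obs], "control_top"),
    control_bottom = observe(ctl$bottom[obs], "control_bottom"),
    incubator = observe(t_inc[obs], "incubator", quantize = FALSE))

  if (config$include_external) {
    spike <- numeric(length(obs))
    dist <- frc$disturbance
    if (!is.null(dist)) {
      n_spk <- stats::rpois(1, dist$rate_per_day * config$duration_days)
      if (n_spk > 0) {
        spk_start <- sort(stats::runif(n_spk, 0, config$duration_days * 86400))
        dur <- (dist$duration_min %||% 5) * 60
        for (s0 in spk_start) {
          hit <- t_sec[obs] >= s0 & t_sec[obs] < s0 + dur
          spike[hit] <- spike[hit] + dist$amplitude
        }
      }
    }
    for (ch in c("living_top_ext", "living_bottom_ext",
                 "control_top_ext", "control_bottom_ext")) {
      rec[[ch]] <- observe(t_inc[obs] + spike, ch)
    }
  }

  # logging gaps: technical interruptions remove whole records
  drop <- rep(FALSE, nrow(rec))
  dp <- sn$dropout
  if (!is.null(dp)) {
    if (is.numeric(dp) && length(dp) == 1L) {
      n_gaps <- stats::rpois(1, dp * config$duration_days)
      if (n_gaps > 0) {
        g0 <- stats::runif(n_gaps, 0, config$duration_days * 86400)
        glen <- stats::runif(n_gaps, 15, 60) * 60
        for (j in seq_len(n_gaps)) {
          drop <- drop | (t_sec[obs] >= g0[j] & t_sec[obs] < g0[j] + glen[j])
        }
      }
    } else {
      for (w in dp) {
        drop <- drop | (ts >= w[[1]] & ts < w[[2]])
      }
    }
  }

  truth <- tibble::tibble(
    timestamp = ts,
    living_top = liv$top[obs], living_bottom = liv$bottom[obs],
    control_top = ctl$top[obs], control_bottom = ctl$bottom[obs],
    incubator = t_inc[obs],
    p_living_top = liv$p_top[obs], p_living_bottom = liv$p_bottom[obs],
    flux_living_top = liv$flux_top[obs], flux_living_bottom = liv$flux_bottom[obs],
    flux_control_top = ctl$flux_top[obs], flux_control_bottom = ctl$flux_bottom[obs],
    light_fraction = frac[obs])

  structure(
    list(log = temp_log(rec[!drop, ], sampling_period = sn$sampling_period),
         truth = truth, config = config),
    class = "column_simulation")
}

#' @export
print.column_simulation <- function(x, ...) {
  cat(sprintf("<column_simulation> %g day(s), seed %d\n",
              x$config$duration_days, x$config$seed))
  print(x$log)
  invisible(x)
}

#' Default instrumented-column scenario
#'
#' A documented, calibrated scenario for end-to-end runs and demos: diurnal
#' 22-30 °C incubator forcing, two identical passive columns except for the
#' living column's microbial sources, a light-modulated top-node source
#' sized (via the steady-state network solution) so the living column's
#' internal top-bottom gradient exceeds the control's by
#' `target_d2_excess` °C under full illumination, plus a small constant
#' bottom source. Sensor offsets default to zero so that column-to-column
#' comparisons reflect the sources; configure `offsets` in the sensor model
#' to study offset confounding.
#'
#' @param days Simulated duration (days).
#' @param seed Integer seed.
#' @param target_d2_excess Target excess of the living internal gradient
#'   over the control's at full light (°C); default 0.25.
#' @param source_bottom Constant bottom-node source (W).
#' @param ... Passed on to [column_sim_config()] (e.g. `sensors`,
#'   `insulation`, `forcing`).
#' @return A [column_sim_config()].
#' @export
scenario_default <- function(days = 7, seed = 1L, target_d2_excess = 0.25,
                             source_bottom = 0.01, ...) {
  ket <- 0.15; keb <- 0.15; kint <- 0.1; kbase <- 0.05
  det <- (ket + kint) * (keb + kbase + kint) - kint^2
  # steady-state gradient excess = [P_top (keb+kbase) - P_bottom ket] / det
  p_top <- (target_d2_excess * det + source_bottom * ket) / (keb + kbase)
  living <- column_thermal_model(
    conduct_ext = c(top = ket, bottom = keb), conduct_int = kint,
    base_loss = kbase, source_top = p_top, source_bottom = source_bottom)
  control <- column_thermal_model(
    conduct_ext = c(top = ket, bottom = keb), conduct_int = kint,
    base_loss = kbase)
  column_sim_config(duration_days = days, living = living, control = control,
                    seed = seed, ...)
}
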