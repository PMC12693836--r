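quiet_forcing <- function(base = 22.2) {
  incubator_forcing(base_temp = base, amplitude = 0, noise_sd = 0)
}

noise_free_sensors <- function() sensor_model(noise_sd = 0)

test_that("a sourceless system at equilibrium stays at the incubator temperature", {
  cfg <- column_sim_config(
    duration_days = 1, forcing = quiet_forcing(),
    living = column_thermal_model(), control = column_thermal_model(),
    sensors = noise_free_sensors(), include_external = FALSE, seed = 5)
  sim <- simulate_columns(cfg)
  for (ch in c("living_top", "living_bottom", "control_top", "control_bottom")) {
    expect_true(all(abs(sim$log$records[[ch]] - 22.2) <= 0.0625))
  }
  expect_true(all(abs(sim$truth$living_top - 22.2) < 1e-9))
})

test_that("a constant source settles at the closed-form P/K offset", {
  # top node decoupled from the bottom: single-node balance, offset P/K_ext
  m <- column_thermal_model(conduct_ext = c(top = 0.05, bottom = 0.15),
                            conduct_int = 0, base_loss = 0,
                            source_top = 0.01,
                            source_top_light_modulated = FALSE)
  cfg <- column_sim_config(duration_days = 3, forcing = quiet_forcing(),
                           living = m, control = column_thermal_model(),
                           sensors = noise_free_sensors(),
                           include_external = FALSE, seed = 5)
  sim <- simulate_columns(cfg)
  final <- tail(sim$truth$living_top, 1)
  expect_equal(final - 22.2, 0.01 / 0.05, tolerance = 0.005)
})

test_that("with no losses the heating rate matches the heat-balance theory", {
  # 1 kg of sediment at c_s = 3200: C = 3200 J/degC, P = 4.58 W
  m <- column_thermal_model(heat_capacity = c(top = 3200, bottom = 3200),
                            conduct_ext = c(top = 0, bottom = 0),
                            conduct_int = 0, base_loss = 0,
                            source_top = 4.58,
                            source_top_light_modulated = FALSE)
  cfg <- column_sim_config(duration_days = 0.25, forcing = quiet_forcing(),
                           living = m, control = column_thermal_model(),
                           sensors = noise_free_sensors(),
                           include_external = FALSE, seed = 5)
  sim <- simulate_columns(cfg)
  tr <- sim$truth
  hours <- as.numeric(diff(range(tr$timestamp)), units = "hours")
  slope <- (tail(tr$living_top, 1) - tr$living_top[1]) / hours
  expect_equal(slope, heating_rate(4.58, 3200), tolerance = 1e-3)
})

test_that("energy bookkeeping closes with noise disabled", {
  cfg <- scenario_default(days = 3, seed = 5,
                          forcing = quiet_forcing(),
                          sensors = noise_free_sensors(),
                          include_external = FALSE)
  sim <- simulate_columns(cfg)
  tr <- sim$truth
  step <- cfg$sensors$sampling_period
  n <- nrow(tr)
  for (node in c("living_top", "living_bottom", "control_top", "control_bottom")) {
    C <- 512
    lhs <- C * (tr[[node]][n] - tr[[node]][1])
    rhs <- step * sum(tr[[paste0("flux_", node)]][-n])
    expect_equal(lhs, rhs, tolerance = abs(rhs) * 1e-3 + 1e-9)
  }
})

test_that("every quantized reading is an exact multiple of the resolution", {
  sim <- simulate_columns(scenario_default(days = 1, seed = 3))
  quantized <- setdiff(sim$log$channels, "incubator")
  for (ch in quantized) {
    steps <- sim$log$records[[ch]] / 0.0625
    expect_true(all(abs(steps - round(steps)) < 1e-9))
  }
})

test_that("identical configurations and seeds give bit-identical logs", {
  a <- simulate_columns(scenario_default(days = 1, seed = 9))
  b <- simulate_columns(scenario_default(days = 1, seed = 9))
  expect_identical(a$log$records, b$log$records)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_temp_log(a$log, fa); write_temp_log(b$log, fb)
  expect_identical(readLines(fa), readLines(fb))
  c_ <- simulate_columns(scenario_default(days = 1, seed = 10))
  expect_false(identical(a$log$records, c_$log$records))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_columns(scenario_default(days = 0.1, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("internal nodes lag the incubator forcing", {
  cfg <- scenario_default(days = 3, seed = 5, sensors = noise_free_sensors(),
                          include_external = FALSE)
  cfg$forcing <- incubator_forcing(noise_sd = 0)
  sim <- simulate_columns(cfg)
  tr <- sim$truth
  lags <- 0:120  # minutes
  cors <- vapply(lags, function(l) {
    n <- nrow(tr)
    cor(tr$incubator[1:(n - l)], tr$control_top[(1 + l):n])
  }, numeric(1))
  expect_gt(which.max(cors) - 1, 0)
})

test_that("the step response tracks the analytic single-node relaxation", {
  # near-instant incubator response and a 1-minute lamp step at noon turn the
  # top node into a clean first-order system
  sched <- tibble::tibble(time = c("00:00", "12:00", "12:01", "24:00"),
                          fraction = c(0, 0, 1, 1))
  frc <- incubator_forcing(base_temp = 22, amplitude = 8,
                           illumination = illumination_spec(schedule = sched),
                           response_tau = 30, noise_sd = 0)
  m <- column_thermal_model(conduct_ext = c(top = 0.15, bottom = 0.15),
                            conduct_int = 0, base_loss = 0.05)
  cfg <- column_sim_config(duration_days = 1, forcing = frc, living = m,
                           control = column_thermal_model(conduct_int = 0),
                           sensors = noise_free_sensors(),
                           include_external = FALSE, step = 30, seed = 5)
  sim <- simulate_columns(cfg)
  tr <- sim$truth
  # forcing settles at 30 degC within two filter steps of 12:01; compare the
  # node trajectory from 12:05 onward against the exact exponential
  t0 <- as.POSIXct("2022-04-01 12:05:00", tz = "UTC")
  post <- tr[tr$timestamp >= t0, ]
  tau <- 512 / 0.15
  dt_sec <- as.numeric(post$timestamp - t0, units = "secs")
  analytic <- 30 - (30 - post$living_top[1]) * exp(-dt_sec / tau)
  expect_lt(max(abs(post$living_top - analytic)), 0.005 * 8)
})

test_that("unstable integration steps are rejected with advice", {
  err <- expect_error(
    column_sim_config(living = column_thermal_model(
      heat_capacity = c(top = 10, bottom = 10)),
      control = column_thermal_model(heat_capacity = c(top = 10, bottom = 10))),
    class = "thermocol_stability_error")
  expect_match(conditionMessage(err), "smaller step")
})

test_that("the control column cannot carry heat sources", {
  expect_error(
    column_sim_config(control = column_thermal_model(source_top = 0.1)),
    class = "thermocol_config_error")
})

test_that("insulation scales external coupling but never the base loss", {
  ev <- insulation_event(as.POSIXct("2022-04-03 09:00:00", tz = "UTC"),
                         as.POSIXct("2022-04-04 09:00:00", tz = "UTC"),
                         conductance_scale = 0.2)
  cfg <- scenario_default(days = 6, seed = 5, insulation = list(ev),
                          sensors = noise_free_sensors(),
                          include_external = FALSE,
                          forcing = quiet_forcing(25))
  sim <- simulate_columns(cfg)
  tr <- sim$truth
  during <- tr$timestamp >= ev$start & tr$timestamp < ev$end
  pre <- tr$timestamp < ev$start & tr$timestamp >= ev$start - 86400
  # weaker coupling lets the sourced living column ride higher above ambient
  excess_pre <- mean(tr$living_top[pre] - tr$incubator[pre])
  excess_during <- mean(tr$living_top[during][-(1:180)] -
                          tr$incubator[during][-(1:180)])
  expect_gt(excess_during, excess_pre * 1.5)
})

test_that("configured dropout windows create logging gaps", {
  gap <- list(c(as.POSIXct("2022-04-01 10:00:00", tz = "UTC"),
                as.POSIXct("2022-04-01 12:00:00", tz = "UTC")))
  cfg <- scenario_default(days = 1, seed = 8,
                          sensors = sensor_model(dropout = gap))
  sim <- simulate_columns(cfg)
  g <- log_gaps(sim$log)
  expect_equal(nrow(g), 1)
  # last record at 09:59, first after the window at 12:00
  expect_equal(as.numeric(g$duration), 2 * 3600 + 60)
})

test_that("the default scenario separates living and control gradients in D2", {
  sim <- simulate_columns(scenario_default(days = 4, seed = 42))
  dl <- daily_phase_means(difference_series(sim$log, "tb_int_living"))
  dc <- daily_phase_means(difference_series(sim$log, "tb_int_control"))
  m <- merge(dl[dl$phase == "D2" & dl$valid, c("day", "mean")],
             dc[dc$phase == "D2" & dc$valid, c("day", "mean")], by = "day")
  expect_gte(nrow(m), 3)
  expect_true(all(m$mean.x > m$mean.y))
  expect_equal(mean(m$mean.x - m$mean.y), 0.25, tolerance = 0.1)
})

test_that("zeroing the sources removes the column difference", {
  cfg <- scenario_default(days = 4, seed = 42, target_d2_excess = 0,
                          source_bottom = 0)
  sim <- simulate_columns(cfg)
  dl <- daily_phase_means(difference_series(sim$log, "tb_int_living"))
  dc <- daily_phase_means(difference_series(sim$log, "tb_int_control"))
  m <- merge(dl[dl$phase == "D2" & dl$valid, c("day", "mean", "n")],
             dc[dc$phase == "D2" & dc$valid, c("day", "mean")], by = "day")
  sigma_eff <- sqrt(0.05^2 + 0.0625^2 / 12)  # reading noise + quantization
  expect_true(all(abs(m$mean.x - m$mean.y) < 3 * 2 * sigma_eff / sqrt(m$n)))
})
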