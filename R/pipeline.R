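write_table_native <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) {
      df[[nm]] <- format(df[[nm]], "%Y-%m-%d %H:%M:%S")
    } else if (inherits(df[[nm]], "Date")) {
      df[[nm]] <- format(df[[nm]])
    } else if (is.numeric(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = 10, format = "g")
    }
  }
  utils::write.table(df, path, sep = ";", quote = FALSE, row.names = FALSE)
  path
}

# Small stable content fingerprint (polynomial hash mod 2^31 - 1 over the
# UTF-8 bytes) for the manifest.
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes ingest, phase segmentation, difference statistics, optional
#' retention analysis, and the binned distribution comparison on either a
#' supplied temperature log or a simulated scenario (exactly one of the
#' two), writing tidy semicolon-delimited tables, optional figures, and a
#' run manifest to `out_dir`.
#'
#' Tables written: `phase_summaries.csv` (per day/phase/channel),
#' `daily_gradients.csv` (per-day phase means per difference kind),
#' `gradient_boxplot_stats.csv`, `monthly_aggregates.csv`,
#' `retention.csv` (when events are given), `disttest.csv`, and
#' `manifest.json`. Figures (when `figures = TRUE` and ggplot2 is
#' installed) mirror the standard views: channel time series, phase
#' boxplots, monthly panels, and retention bars with the sensor-precision
#' dashed line. Numeric tables are the authoritative outputs.
#'
#' @param log A [temp_log()], or `NULL` when simulating.
#' @param scenario A [column_sim_config()], or `NULL` when a log is given.
#' @param out_dir Output directory (created if needed).
#' @param schedule A [phase_schedule()].
#' @param events List of [insulation_event()]s to analyse for retention.
#'   When simulating, events configured in the scenario are used by default.
#' @param analyses Character subset of
#'   `c("gradients", "longterm", "retention", "disttest")`.
#' @param sensor A [sensor_spec()] for precision flags.
#' @param min_coverage Valid-day coverage threshold.
#' @param figures Write figures (requires ggplot2).
#' @return Invisibly, a list of the computed tables plus `paths`.
#' @export
run_pipeline <- function(log = NULL, scenario = NULL, out_dir,
                         schedule = phase_schedule(), events = NULL,
                         analyses = c("gradients", "longterm",
                                      "retention", "disttest"),
                         sensor = sensor_spec(), min_coverage = 0.9,
                         figures = FALSE) {
  if (is.null(log) == is.null(scenario)) {
    stop_thermocol("supply exactly one of `log` or `scenario`",
                   "thermocol_config_error")
  }
  sim <- NULL
  if (!is.null(scenario)) {
    sim <- simulate_columns(scenario)
    log <- sim$log
    if (is.null(events) && length(scenario$insulation) > 0) {
      events <- scenario$insulation
    }
  }
  stopifnot(inherits(log, "temp_log"))
  if (nrow(log$records) == 0L) {
    stop_thermocol("no input datasets", "thermocol_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  out <- list()
  sp <- log$sampling_period

  out$phase_summaries <- summarize_phases(log, schedule)
  paths["phase_summaries"] <- write_table_native(
    out$phase_summaries, file.path(out_dir, "phase_summaries.csv"))

  kinds <- difference_kinds()
  kinds <- kinds[kinds$minuend %in% log$channels &
                   kinds$subtrahend %in% log$channels, ]
  series <- lapply(kinds$kind, function(kk) difference_series(log, kk))
  names(series) <- kinds$kind

  if ("gradients" %in% analyses && length(series) > 0) {
    daily <- dplyr::bind_rows(lapply(names(series), function(kk) {
      d <- daily_phase_means(series[[kk]], schedule, sp, min_coverage)
      d$kind <- kk
      d
    }))
    out$daily_gradients <- daily[, c("kind", "day", "phase", "mean", "sd",
                                     "n", "valid")]
    paths["daily_gradients"] <- write_table_native(
      out$daily_gradients, file.path(out_dir, "daily_gradients.csv"))

    box <- dplyr::bind_rows(lapply(names(series), function(kk) {
      dplyr::bind_rows(lapply(analysis_phases(schedule), function(ph) {
        b <- suppressWarnings(
          phase_boxplot_stats(series[[kk]], schedule, ph, sp, min_coverage))
        if (nrow(b)) b$kind <- kk
        b
      }))
    }))
    out$gradient_boxplot_stats <- box
    paths["gradient_boxplot_stats"] <- write_table_native(
      box, file.path(out_dir, "gradient_boxplot_stats.csv"))
  }

  if ("longterm" %in% analyses) {
    diff_summaries <- dplyr::bind_rows(
      lapply(series, summarize_phases, schedule = schedule))
    all_summaries <- dplyr::bind_rows(out$phase_summaries, diff_summaries)
    combos <- expand.grid(
      channel = unique(all_summaries$channel),
      phase = analysis_phases(schedule), stringsAsFactors = FALSE)
    monthly <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
      monthly_aggregate(all_summaries, combos$channel[i], combos$phase[i],
                        schedule, sp, min_coverage)
    }))
    out$monthly_aggregates <- monthly
    paths["monthly_aggregates"] <- write_table_native(
      monthly, file.path(out_dir, "monthly_aggregates.csv"))
  }

  if ("retention" %in% analyses && length(events) > 0) {
    ret <- dplyr::bind_rows(lapply(events, function(ev) {
      dplyr::bind_rows(lapply(intersect(c("top", "bottom"), names(series)),
                              function(kk) {
        r <- retention_stats(series[[kk]], ev, schedule,
                             sampling_period = sp, min_coverage = min_coverage)
        r$wrap <- ev$wrap
        r
      }))
    }))
    ret <- precision_flag(ret, sensor)
    out$retention <- ret
    paths["retention"] <- write_table_native(
      ret, file.path(out_dir, "retention.csv"))
  }

  if ("disttest" %in% analyses &&
      all(c("tb_int_living", "tb_int_control") %in% names(series))) {
    comparisons <- list(
      internal_gradient = c("tb_int_living", "tb_int_control"))
    if (all(c("tb_ext_living", "tb_ext_control") %in% names(series))) {
      comparisons$external_gradient <- c("tb_ext_living", "tb_ext_control")
    }
    dt <- dplyr::bind_rows(lapply(names(comparisons), function(nm) {
      pair <- comparisons[[nm]]
      ba <- bin_differences(series[[pair[1]]]$samples$value)
      bb <- bin_differences(series[[pair[2]]]$samples$value)
      r <- mwu_binned(ba, bb)
      tibble::tibble(comparison = nm, a = pair[1], b = pair[2],
                     U = r$U, p_value = r$p_value, method = r$method,
                     n_outside_a = ba$n_outside, n_outside_b = bb$n_outside)
    }))
    out$disttest <- dt
    paths["disttest"] <- write_table_native(
      dt, file.path(out_dir, "disttest.csv"))
  }

  if (isTRUE(figures)) {
    paths <- c(paths, pipeline_figures(log, series, out, out_dir, schedule,
                                       sensor))
  }

  cfg <- list(
    package_version = as.character(utils::packageVersion("thermocol")),
    input = if (is.null(sim)) "log" else "simulation",
    seed = if (is.null(sim)) NA else sim$config$seed,
    sampling_period = sp,
    min_coverage = min_coverage,
    analyses = analyses,
    schedule = as.data.frame(schedule$intervals),
    n_records = nrow(log$records),
    channels = log$channels)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = cfg, config_hash = content_hash(as.character(cfg_json)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["manifest"] <- manifest_path
  out$paths <- paths
  invisible(out)
}

pipeline_figures <- function(log, series, tables, out_dir, schedule, sensor) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not installed; skipping figures")
    return(character())
  }
  paths <- character()
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes

  long <- tidyr::pivot_longer(log$records, dplyr::all_of(log$channels),
                              names_to = "channel", values_to = "temperature")
  p1 <- gg(long[!is.na(long$temperature), ],
           aes(x = .data$timestamp, y = .data$temperature,
               colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "Temperature (degC)")
  f1 <- file.path(out_dir, "timeseries.png")
  ggplot2::ggsave(f1, p1, width = 9, height = 4, dpi = 120)
  paths["fig_timeseries"] <- f1

  if (!is.null(tables$daily_gradients)) {
    dg <- tables$daily_gradients
    dg <- dg[dg$valid, ]
    p2 <- gg(dg, aes(x = .data$phase, y = .data$mean)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~kind, scales = "free_y") +
      ggplot2::labs(x = "Phase", y = "Per-day phase mean (degC)")
    f2 <- file.path(out_dir, "phase_boxplots.png")
    ggplot2::ggsave(f2, p2, width = 8, height = 5, dpi = 120)
    paths["fig_phase_boxplots"] <- f2
  }

  if (!is.null(tables$monthly_aggregates) &&
      nrow(tables$monthly_aggregates) > 0) {
    ma <- tables$monthly_aggregates
    p3 <- gg(ma, aes(x = .data$month, y = .data$mean)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(aes(ymin = .data$mean - .data$sd,
                                 ymax = .data$mean + .data$sd), width = 0.2) +
      ggplot2::facet_grid(channel ~ phase, scales = "free_y") +
      ggplot2::labs(x = "Month", y = "Mean (degC)")
    f3 <- file.path(out_dir, "monthly_panels.png")
    ggplot2::ggsave(f3, p3, width = 10, height = 8, dpi = 120)
    paths["fig_monthly_panels"] <- f3
  }

  if (!is.null(tables$retention) && nrow(tables$retention) > 0) {
    rt <- tidyr::pivot_longer(tables$retention,
                              c("delta_delta", "delta_delta_steady"),
                              names_to = "statistic", values_to = "value")
    p4 <- gg(rt, aes(x = .data$phase, y = .data$value)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = c(-1, 1) * sensor$resolution,
                          linetype = "dashed") +
      ggplot2::facet_grid(region ~ statistic) +
      ggplot2::labs(x = "Phase", y = "Change in temperature difference (degC)")
    f4 <- file.path(out_dir, "retention_bars.png")
    ggplot2::ggsave(f4, p4, width = 8, height = 5, dpi = 120)
    paths["fig_retention_bars"] <- f4
  }
  paths
}
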