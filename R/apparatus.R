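#' Column geometry
#'
#' Describes one sediment column: a transparent cylinder sealed at the bottom,
#' filled with sediment and closed with a stoppered top through which the
#' temperature probes enter.
#'
#' @param inner_diameter Inner diameter of the cylinder (cm).
#' @param height Cylinder height (cm).
#' @param fill_volume Total sediment volume in the column (mL).
#' @param enriched_volume Volume of the enriched bottom layer (mL); must not
#'   exceed `fill_volume`.
#'
#' @return An object of class `column_geometry`.
#' @examples
#' column_geometry()
#' @export
column_geometry <- function(inner_diameter = 4, height = 20,
                            fill_volume = 200, enriched_volume = 50) {
  check_number(inner_diameter, "inner_diameter", min = 0, strict_min = TRUE)
  check_number(height, "height", min = 0, strict_min = TRUE)
  check_number(fill_volume, "fill_volume", min = 0, strict_min = TRUE)
  check_number(enriched_volume, "enriched_volume", min = 0)
  if (enriched_volume > fill_volume) {
    stop_thermocol("`enriched_volume` must not exceed `fill_volume`",
                   "thermocol_invalid_geometry")
  }
  capacity <- pi * (inner_diameter / 2)^2 * height # cm^3 == mL
  if (fill_volume > capacity + 1e-9) {
    stop_thermocol(
      sprintf("`fill_volume` (%g mL) exceeds the cylinder capacity (%.1f mL)",
              fill_volume, capacity),
      "thermocol_invalid_geometry")
  }
  structure(
    list(inner_diameter = inner_diameter, height = height,
         fill_volume = fill_volume, enriched_volume = enriched_volume),
    class = "column_geometry")
}

#' @export
print.column_geometry <- function(x, ...) {
  cat(sprintf(
    "<column_geometry> ID %g cm x %g cm, fill %g mL (enriched layer %g mL)\n",
    x$inner_diameter, x$height, x$fill_volume, x$enriched_volume))
  invisible(x)
}

#' Illumination specification
#'
#' The lamp bank above the incubator and its 24-h dimming program. The
#' `schedule` is a set of (clock time, intensity fraction) breakpoints that
#' are linearly interpolated over the day; it must start at 00:00 and end at
#' 24:00 so it covers the full cycle.
#'
#' The default program ramps from moonlight (1.9 %) up to full power between
#' 07:00 and 08:00, holds 100 % until midnight, and dims back to moonlight by
#' 01:00 — an 18 h light / 6 h dark cycle.
#'
#' @param lamp_count Number of identical lamps.
#' @param photon_flux_per_lamp Photon flux per lamp (µmol s⁻¹).
#' @param footprint_length,footprint_width Illuminated incubator footprint (m).
#' @param schedule Data frame with columns `time` ("HH:MM") and `fraction`
#'   (in \[0, 1\]).
#'
#' @return An object of class `illumination_spec`.
#' @examples
#' spec <- illumination_spec()
#' total_photon_flux(spec)
#' @export
illumination_spec <- function(lamp_count = 3, photon_flux_per_lamp = 43.91,
                              footprint_length = 0.72, footprint_width = 0.55,
                              schedule = default_light_schedule()) {
  if (!is.numeric(lamp_count) || length(lamp_count) != 1L || lamp_count < 1 ||
      lamp_count != round(lamp_count)) {
    stop_thermocol("`lamp_count` must be a whole number >= 1",
                   "thermocol_domain_error")
  }
  check_number(photon_flux_per_lamp, "photon_flux_per_lamp", min = 0, strict_min = TRUE)
  check_number(footprint_length, "footprint_length", min = 0)
  check_number(footprint_width, "footprint_width", min = 0)
  stopifnot(is.data.frame(schedule), all(c("time", "fraction") %in% names(schedule)))
  mins <- clock_to_min(schedule$time)
  if (any(schedule$fraction < 0 | schedule$fraction > 1)) {
    stop_thermocol("schedule intensity fractions must lie in [0, 1]",
                   "thermocol_domain_error")
  }
  if (is.unsorted(mins) || mins[1] != 0 || mins[length(mins)] != 1440) {
    stop_thermocol("schedule breakpoints must be sorted and cover 00:00-24:00",
                   "thermocol_config_error")
  }
  structure(
    list(lamp_count = as.integer(lamp_count),
         photon_flux_per_lamp = photon_flux_per_lamp,
         footprint_length = footprint_length,
         footprint_width = footprint_width,
         schedule = tibble::as_tibble(schedule)),
    class = "illumination_spec")
}

#' Default 24-h dimming program
#'
#' Breakpoints of the diel lamp program: full power through the evening,
#' dimming to 1.9 % "moonlight" between 00:00 and 01:00, holding moonlight
#' until 07:00, and ramping back to full power by 08:00.
#'
#' @return A tibble with columns `time` and `fraction`.
#' @export
default_light_schedule <- function() {
  tibble::tibble(
    time = c("00:00", "01:00", "07:00", "08:00", "24:00"),
    fraction = c(1, 0.019, 0.019, 1, 1))
}

#' Lamp intensity fraction at given times of day
#'
#' Linear interpolation of the schedule breakpoints.
#'
#' @param spec An [illumination_spec()].
#' @param minute Minutes since midnight (vectorised, values in \[0, 1440\]).
#' @return Intensity fractions in \[0, 1\].
#' @export
light_fraction <- function(spec, minute) {
  stopifnot(inherits(spec, "illumination_spec"))
  mins <- clock_to_min(spec$schedule$time)
  stats::approx(mins, spec$schedule$fraction, xout = minute %% 1440,
                rule = 2)$y
}

#' Sensor specification
#'
#' Resolution (quantization step), accuracy bound, and ADC bit depth of the
#' embedded digital thermometers. At the 12-bit default the probes step in
#' 0.0625 °C increments with a ±0.5 °C accuracy bound.
#'
#' @param resolution Quantization step (°C per least-significant bit).
#' @param accuracy Accuracy bound (± °C); must be at least the resolution.
#' @param bit_depth ADC bit depth (9-12).
#' @return An object of class `sensor_spec`.
#' @examples
#' sensor_spec()
#' @export
sensor_spec <- function(resolution = quantization_step(bit_depth),
                        accuracy = 0.5, bit_depth = 12) {
  check_number(resolution, "resolution", min = 0, strict_min = TRUE)
  check_number(accuracy, "accuracy", min = 0)
  if (accuracy < resolution) {
    stop_thermocol("`accuracy` must be at least `resolution`",
                   "thermocol_domain_error")
  }
  structure(list(resolution = resolution, accuracy = accuracy,
                 bit_depth = as.integer(bit_depth)),
            class = "sensor_spec")
}

#' Fill height of a volume in a column
#'
#' Height reached by a given volume in the cylinder:
#' `volume / (pi * (inner_diameter / 2)^2)`. The raw value is returned;
#' rounding for display is the caller's concern.
#'
#' @param volume Volume (mL).
#' @param geometry A [column_geometry()].
#' @return Height (cm).
#' @examples
#' fill_height(50, column_geometry())  # ~ 4 cm enriched layer
#' @export
fill_height <- function(volume, geometry) {
  stopifnot(inherits(geometry, "column_geometry"))
  check_number(volume, "volume", min = 0)
  if (geometry$inner_diameter <= 0) {
    stop_thermocol("inner diameter must be positive", "thermocol_invalid_geometry")
  }
  volume / (pi * (geometry$inner_diameter / 2)^2)
}

#' Total photon flux of the lamp bank
#'
#' @param spec An [illumination_spec()].
#' @return Total flux (µmol s⁻¹): `lamp_count * photon_flux_per_lamp`.
#' @export
total_photon_flux <- function(spec) {
  stopifnot(inherits(spec, "illumination_spec"))
  spec$lamp_count * spec$photon_flux_per_lamp
}

#' Mean irradiance over the incubator footprint
#'
#' @param spec An [illumination_spec()].
#' @return Mean photon irradiance (µmol m⁻² s⁻¹).
#' @export
mean_irradiance <- function(spec) {
  stopifnot(inherits(spec, "illumination_spec"))
  area <- spec$footprint_length * spec$footprint_width
  if (area <= 0) {
    stop_thermocol("footprint area must be positive", "thermocol_invalid_geometry")
  }
  total_photon_flux(spec) / area
}

#' Quantization step of the digital thermometer
#'
#' The sensor family dedicates `bit_depth - 8` bits to the fractional part of
#' the temperature word, so the step is `2^-(bit_depth - 8)` °C.
#'
#' @param bit_depth ADC bit depth; one of 9, 10, 11, 12.
#' @return Step size (°C).
#' @examples
#' quantization_step(12)  # 0.0625
#' @export
quantization_step <- function(bit_depth) {
  if (!is.numeric(bit_depth) || length(bit_depth) != 1L ||
      !(bit_depth %in% 9:12)) {
    stop_thermocol("`bit_depth` must be one of 9, 10, 11, 12",
                   "thermocol_config_error")
  }
  2^-(bit_depth - 8)
}
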