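#' Sediment composition and heat-capacity bounds
#'
#' Water content and heat-capacity inputs for the heat-balance estimate. The
#' default water mass fraction of 0.618 comes from gravimetric drying of the
#' source sediment (dry-to-fresh ratio 38.2 %); the bulk heat-capacity range
#' `c_s_range` of 2880-4180 J kg⁻¹ °C⁻¹ is the working range used by the
#' heating-rate predictions. The mass-weighted mixture calculator
#' [mixture_heat_capacity()] is provided for sensitivity analysis but is not
#' used to re-derive `c_s_range`, which is an independently sourced bound.
#'
#' @param water_mass_fraction Water mass fraction of fresh sediment, in \[0, 1\].
#' @param dry_to_fresh_ratio Dry-to-fresh mass ratio, in \[0, 1\]. When both
#'   fractions are given they must sum to 1 within 0.01.
#' @param c_dry_range Dry-sediment specific heat range (J kg⁻¹ °C⁻¹).
#' @param c_water Specific heat of water (J kg⁻¹ °C⁻¹).
#' @param c_s_range Bulk sediment specific heat range (J kg⁻¹ °C⁻¹).
#' @return An object of class `sediment_composition`.
#' @export
sediment_composition <- function(water_mass_fraction = 0.618,
                                 dry_to_fresh_ratio = 0.382,
                                 c_dry_range = c(910, 2400),
                                 c_water = 4184,
                                 c_s_range = c(2880, 4180)) {
  check_number(water_mass_fraction, "water_mass_fraction", min = 0, max = 1)
  check_number(dry_to_fresh_ratio, "dry_to_fresh_ratio", min = 0, max = 1)
  if (abs(water_mass_fraction + dry_to_fresh_ratio - 1) > 0.01) {
    stop_thermocol(
      "`water_mass_fraction` and `dry_to_fresh_ratio` must sum to 1 (tolerance 0.01)",
      "thermocol_domain_error")
  }
  for (r in list(c_dry_range = c_dry_range, c_s_range = c_s_range)) {
    stopifnot(length(r) == 2L, all(r > 0), r[1] <= r[2])
  }
  check_number(c_water, "c_water", min = 0, strict_min = TRUE)
  structure(
    list(water_mass_fraction = water_mass_fraction,
         dry_to_fresh_ratio = dry_to_fresh_ratio,
         c_dry_range = c_dry_range, c_water = c_water, c_s_range = c_s_range),
    class = "sediment_composition")
}

#' Per-cell heat rates and cell abundance
#'
#' Metabolic heat produced per cell under aerobic and anaerobic growth
#' (defaults 0.8 and 0.2 pW per cell for the *E. coli* reference organism)
#' and the assumed cell abundance per kilogram of sediment. The default
#' abundance of 5.725e12 cells kg⁻¹ is the value implied by the aerobic
#' volumetric power density of 4.58 W kg⁻¹ used by the prediction.
#'
#' @param q_aerobic,q_anaerobic Heat rate per cell (W); aerobic must exceed
#'   anaerobic and both must be positive.
#' @param abundance Cells per kg of sediment.
#' @return An object of class `cell_heat_spec`.
#' @export
cell_heat_spec <- function(q_aerobic = 0.8e-12, q_anaerobic = 0.2e-12,
                           abundance = 5.725e12) {
  check_number(q_aerobic, "q_aerobic", min = 0, strict_min = TRUE)
  check_number(q_anaerobic, "q_anaerobic", min = 0, strict_min = TRUE)
  if (q_aerobic <= q_anaerobic) {
    stop_thermocol("`q_aerobic` must exceed `q_anaerobic`", "thermocol_domain_error")
  }
  check_number(abundance, "abundance", min = 0)
  structure(list(q_aerobic = q_aerobic, q_anaerobic = q_anaerobic,
                 abundance = abundance),
            class = "cell_heat_spec")
}

#' Mass-weighted mixture heat capacity
#'
#' `w * c_water + (1 - w) * c_dry` for water mass fraction `w`. Monotone
#' increasing in `w` whenever water is the more heat-capacious component.
#'
#' @param water_mass_fraction Water mass fraction in \[0, 1\].
#' @param c_dry Dry-solid specific heat (J kg⁻¹ °C⁻¹).
#' @param c_water Water specific heat (J kg⁻¹ °C⁻¹), default 4184.
#' @return Mixture specific heat (J kg⁻¹ °C⁻¹).
#' @examples
#' mixture_heat_capacity(0.62, 910)
#' @export
mixture_heat_capacity <- function(water_mass_fraction, c_dry, c_water = 4184) {
  check_number(water_mass_fraction, "water_mass_fraction", min = 0, max = 1)
  check_number(c_dry, "c_dry", min = 0, strict_min = TRUE)
  check_number(c_water, "c_water", min = 0, strict_min = TRUE)
  water_mass_fraction * c_water + (1 - water_mass_fraction) * c_dry
}

#' Volumetric metabolic power density
#'
#' Heat produced per kilogram of sediment: per-cell heat rate times cell
#' abundance. With the defaults this reproduces the aerobic and anaerobic
#' coefficients 4.58 and 1.145 W kg⁻¹ of the heating-rate relation.
#'
#' @param spec A [cell_heat_spec()].
#' @param condition `"aerobic"` or `"anaerobic"`.
#' @return Power density (W kg⁻¹).
#' @export
power_density <- function(spec, condition = c("aerobic", "anaerobic")) {
  stopifnot(inherits(spec, "cell_heat_spec"))
  condition <- match.arg(condition)
  q <- switch(condition, aerobic = spec$q_aerobic, anaerobic = spec$q_anaerobic)
  q * spec$abundance
}

#' Adiabatic sediment heating rate
#'
#' The lumped heat balance `P = c_s * dT/dt` per unit mass gives
#' `dT/dt = P / c_s` (°C s⁻¹), reported per hour. This is an idealized upper
#' limit: conductive and convective losses are deliberately excluded.
#'
#' @param power_density Metabolic power density (W kg⁻¹).
#' @param c_s Sediment specific heat (J kg⁻¹ °C⁻¹).
#' @return Heating rate (°C h⁻¹).
#' @examples
#' heating_rate(4.58, 4180)  # ~3.9 degC/h, aerobic lower bound
#' @export
heating_rate <- function(power_density, c_s) {
  check_number(power_density, "power_density", min = 0)
  check_number(c_s, "c_s", min = 0, strict_min = TRUE)
  power_density / c_s * 3600
}

#' Heating-rate prediction over a heat-capacity range
#'
#' Computes the power density for a growth condition and the heating-rate
#' range implied by the sediment heat-capacity bounds (low rate at the high
#' capacity, high rate at the low capacity).
#'
#' @param cells A [cell_heat_spec()].
#' @param condition `"aerobic"` or `"anaerobic"`.
#' @param c_s_range Length-2 numeric, sediment heat-capacity bounds
#'   (J kg⁻¹ °C⁻¹).
#' @return An object of class `heating_rate_prediction` with fields
#'   `power_density`, `rate_range` (°C h⁻¹, low then high), `condition`,
#'   and `c_s_range`.
#' @export
heating_rate_prediction <- function(cells = cell_heat_spec(),
                                    condition = c("aerobic", "anaerobic"),
                                    c_s_range = sediment_composition()$c_s_range) {
  condition <- match.arg(condition)
  stopifnot(length(c_s_range) == 2L, all(c_s_range > 0), c_s_range[1] <= c_s_range[2])
  pd <- power_density(cells, condition)
  rates <- c(heating_rate(pd, c_s_range[2]), heating_rate(pd, c_s_range[1]))
  structure(
    list(power_density = pd, rate_range = rates, condition = condition,
         c_s_range = c_s_range),
    class = "heating_rate_prediction")
}

#' @export
print.heating_rate_prediction <- function(x, ...) {
  cat(sprintf(
    "<heating_rate_prediction> %s: %.3f W/kg -> %.2f-%.2f degC/h (c_s %g-%g J/kg/degC)\n",
    x$condition, x$power_density, x$rate_range[1], x$rate_range[2],
    x$c_s_range[1], x$c_s_range[2]))
  invisible(x)
}

#' Aerobic-minus-anaerobic heating-rate gap
#'
#' Element-wise difference of the two rate ranges, the predicted vertical
#' temperature difference that would build per hour between an aerobic top
#' layer and an anaerobic bottom layer under the idealized no-loss model.
#'
#' @param aerobic,anaerobic [heating_rate_prediction()] objects computed over
#'   the same heat-capacity range.
#' @return Length-2 numeric (low, high) gap (°C h⁻¹).
#' @export
aerobic_anaerobic_gap <- function(aerobic, anaerobic) {
  stopifnot(inherits(aerobic, "heating_rate_prediction"),
            inherits(anaerobic, "heating_rate_prediction"))
  if (!isTRUE(all.equal(aerobic$c_s_range, anaerobic$c_s_range))) {
    stop_thermocol("predictions use different heat-capacity ranges",
                   "thermocol_inconsistency_error")
  }
  aerobic$rate_range - anaerobic$rate_range
}

#' Theory prediction table
#'
#' One row per growth condition with the power density, the computed
#' heating-rate range, and — when nominal reference bounds are supplied —
#' a consistency flag comparing each computed bound to the reference at its
#' printed precision (1 decimal place). With the defaults, the computed
#' upper bounds (5.7 and 1.4 °C h⁻¹) disagree at the last printed digit with
#' the commonly quoted reference bounds (5.6 and 1.3 °C h⁻¹), and the table
#' flags them; the lower bounds agree.
#'
#' @param cells A [cell_heat_spec()].
#' @param composition A [sediment_composition()]; supplies `c_s_range`.
#' @param reference_rates Optional named list of length-2 numeric reference
#'   ranges per condition (°C h⁻¹), or `NULL` to skip the comparison.
#' @return A tibble with columns `condition`, `power_density`, `rate_low`,
#'   `rate_high`, and (if references are given) `ref_low`, `ref_high`,
#'   `low_consistent`, `high_consistent`. The aerobic-minus-anaerobic gap
#'   range is attached as attribute `"gap_range"`.
#' @export
theory_prediction_table <- function(cells = cell_heat_spec(),
                                    composition = sediment_composition(),
                                    reference_rates = list(
                                      aerobic = c(3.9, 5.6),
                                      anaerobic = c(0.9, 1.3))) {
  preds <- lapply(c("aerobic", "anaerobic"), function(cond) {
    heating_rate_prediction(cells, cond, composition$c_s_range)
  })
  tab <- tibble::tibble(
    condition = vapply(preds, `[[`, "", "condition"),
    power_density = vapply(preds, `[[`, 0, "power_density"),
    rate_low = vapply(preds, function(p) p$rate_range[1], 0),
    rate_high = vapply(preds, function(p) p$rate_range[2], 0))
  if (!is.null(reference_rates)) {
    ref <- do.call(rbind, reference_rates[tab$condition])
    tab$ref_low <- ref[, 1]
    tab$ref_high <- ref[, 2]
    tab$low_consistent <- round(tab$rate_low, 1) == round(tab$ref_low, 1)
    tab$high_consistent <- round(tab$rate_high, 1) == round(tab$ref_high, 1)
  }
  attr(tab, "gap_range") <- aerobic_anaerobic_gap(preds[[1]], preds[[2]])
  tab
}

#' Drying series for gravimetric water content
#'
#' Ordered balance readings of one sediment subsample during oven drying.
#'
#' @param sample_id Label for the subsample.
#' @param tare_mass Mass of the empty dish (g).
#' @param time Reading times (any ordered numeric or datetime vector).
#' @param gross_mass Gross masses (dish + sample, g), same length as `time`.
#' @return An object of class `drying_series`.
#' @export
drying_series <- function(sample_id, tare_mass, time, gross_mass) {
  check_number(tare_mass, "tare_mass", min = 0)
  stopifnot(length(time) == length(gross_mass), length(gross_mass) >= 2L)
  if (any(gross_mass <= tare_mass)) {
    stop_thermocol("gross masses must exceed the tare mass", "thermocol_domain_error")
  }
  if (any(diff(gross_mass) > 1e-6)) {
    stop_thermocol("drying masses must be non-increasing", "thermocol_domain_error")
  }
  structure(list(sample_id = as.character(sample_id), tare_mass = tare_mass,
                 time = time, gross_mass = as.numeric(gross_mass)),
            class = "drying_series")
}

#' Gravimetric water content from a drying series
#'
#' Net masses are gross minus tare. Drying is considered complete at the
#' first reading whose change from its predecessor is at most
#' `convergence_delta`; the dry-to-fresh ratio is that reading's net mass
#' over the initial net mass, and the water fraction is its complement.
#'
#' @param series A [drying_series()].
#' @param convergence_delta Largest successive mass change (g) accepted as
#'   "no further weight change". Default 0.01 g.
#' @return A list with `dry_fraction`, `water_fraction`, `final_net_mass`,
#'   `initial_net_mass`, and `converged_at` (index of the converged reading).
#' @examples
#' s <- drying_series("s1", 2, 1:5, 2 + c(10, 6, 4, 3.82, 3.82))
#' water_content_from_drying(s)$dry_fraction  # 0.382
#' @export
water_content_from_drying <- function(series, convergence_delta = 0.01) {
  stopifnot(inherits(series, "drying_series"))
  check_number(convergence_delta, "convergence_delta", min = 0)
  net <- series$gross_mass - series$tare_mass
  deltas <- abs(diff(net))
  idx <- which(deltas <= convergence_delta)
  if (length(idx) == 0L) {
    stop_thermocol(
      sprintf("drying did not converge: last mass change %.4g g exceeds delta %.4g g",
              deltas[length(deltas)], convergence_delta),
      "thermocol_nonconvergence_error")
  }
  at <- idx[1] + 1L
  dry <- net[at] / net[1]
  list(dry_fraction = dry, water_fraction = 1 - dry,
       final_net_mass = net[at], initial_net_mass = net[1], converged_at = at)
}
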