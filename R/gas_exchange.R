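# Net CO2 assimilation, transpiration, bare-soil reference correction,
# and the psychrometric / evaporative-cooling energy-balance helpers.

# specific gas constants, J kg-1 K-1
R_DRY <- 287.058
R_VAPOR <- 461.52
# hydrogen-atom monoisotopic mass is in mass_assignment.R; here only
# thermodynamics constants are needed.

#' Saturation vapor pressure of water (Magnus correlation)
#'
#' `e_s = 610.94 * exp(17.625 t / (t + 243.04))` Pa with `t` in degrees
#' Celsius (Alduchov-Eskridge coefficients); accurate to ~0.4 % between
#' -40 and +50 degrees C.
#'
#' @param temperature_K Air temperature, kelvin (233 K < T < 333 K).
#' @return Saturation vapor pressure, Pa.
#' @examples
#' saturation_vapor_pressure(273.15)  # ~ 611 Pa
#' @export
saturation_vapor_pressure <- function(temperature_K) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 233) ||
      any(temperature_K >= 333))
    cf_stop_invalid("`temperature_K` must be in (233, 333) K for the Magnus form")
  t <- temperature_K - 273.15
  610.94 * exp(17.625 * t / (t + 243.04))
}

#' Absolute humidity of moist air
#'
#' Water-vapor molar concentration `RH * e_s(T) / (R T)` assuming
#' ideal-gas vapor.
#'
#' @param state A [psychrometric_state()].
#' @return Absolute humidity, mol m-3.
#' @export
absolute_humidity <- function(state) {
  if (!inherits(state, "psychrometric_state"))
    cf_stop_input("`state` must be a psychrometric_state")
  state$relative_humidity * saturation_vapor_pressure(state$temperature_K) /
    (R_GAS * state$temperature_K)
}

#' Moist-air density (two-component ideal gas)
#'
#' Dry-air partial pressure over `R_dry T` plus vapor pressure over
#' `R_vapor T`. Note: at 96 kPa, 298.15 K, 80 % RH this gives
#' ~1.11 kg m-3; energy-balance calculations that must reproduce a
#' specific published density should pass that density explicitly to
#' [evaporative_delta_T()].
#'
#' @param state A [psychrometric_state()].
#' @return Air density, kg m-3.
#' @export
air_density <- function(state) {
  if (!inherits(state, "psychrometric_state"))
    cf_stop_input("`state` must be a psychrometric_state")
  e <- state$relative_humidity * saturation_vapor_pressure(state$temperature_K)
  (state$pressure_Pa - e) / (R_DRY * state$temperature_K) +
    e / (R_VAPOR * state$temperature_K)
}

#' Moist-air specific heat capacity
#'
#' Mass-weighted mixture `(c_p,dry + w c_p,vapor) / (1 + w)` with the
#' humidity ratio `w` from the psychrometric state
#' (`c_p,dry` = 1005, `c_p,vapor` = 1864 J kg-1 K-1). Provided for
#' completeness; like [air_density()] it will not reproduce every
#' published c_p — [evaporative_delta_T()] takes c_p as an explicit
#' input for that reason.
#'
#' @param state A [psychrometric_state()].
#' @return Specific heat capacity, J kg-1 K-1.
#' @export
moist_air_cp <- function(state) {
  if (!inherits(state, "psychrometric_state"))
    cf_stop_input("`state` must be a psychrometric_state")
  e <- state$relative_humidity * saturation_vapor_pressure(state$temperature_K)
  w <- 0.62198 * e / (state$pressure_Pa - e)  # kg vapor per kg dry air
  (1005 + w * 1864) / (1 + w)
}

#' Latent heat of vaporization of water (Clausius-Clapeyron)
#'
#' `H_v = R T^2 d(ln e_s)/dT`, with the slope evaluated analytically
#' from the Magnus correlation:
#' `d(ln e_s)/dT = 17.625 * 243.04 / (t + 243.04)^2`, `t` in Celsius.
#' At 298.15 K this gives 44.07 kJ mol-1 (within 0.2 % of the commonly
#' used 43.99 kJ mol-1).
#'
#' @param temperature_K Temperature, kelvin (273-373 K).
#' @return Molar latent heat, J mol-1.
#' @export
latent_heat_vaporization <- function(temperature_K) {
  if (any(!is.finite(temperature_K)) || any(temperature_K < 273) ||
      any(temperature_K > 373.2))
    cf_stop_invalid("`temperature_K` must be within [273, 373] K")
  t <- temperature_K - 273.15
  dlog_es_dT <- 17.625 * 243.04 / (t + 243.04)^2
  R_GAS * temperature_K^2 * dlog_es_dT
}

#' Net CO2 assimilation rate from inlet/outlet mixing ratios
#'
#' The molar air flow through the cuvette is `F_in P / (R T)`; the CO2
#' drawdown `co2_in - co2_out` (umol mol-1) times that flow, per leaf
#' area, is the net assimilation. Positive = net uptake.
#'
#' @param co2_in_ppm,co2_out_ppm CO2 mixing ratios, umol mol-1
#'   (vectors allowed, recycled).
#' @param inlet_flow_lpm Inlet flow, liters per minute.
#' @param leaf_area_m2 Enclosed leaf area, m2 (> 0).
#' @param state A [psychrometric_state()] giving cuvette air temperature
#'   and pressure (leaf temperature is approximated by cuvette air
#'   temperature).
#' @return Net assimilation, umol m-2 s-1.
#' @examples
#' st <- psychrometric_state(298.15, 96000)
#' net_co2_assimilation(400, 390, 6, 0.05, st)  # ~0.77 umol m-2 s-1
#' @export
net_co2_assimilation <- function(co2_in_ppm, co2_out_ppm, inlet_flow_lpm,
                                 leaf_area_m2, state) {
  if (!is.finite(leaf_area_m2) || leaf_area_m2 <= 0)
    cf_stop_invalid("`leaf_area_m2` must be > 0 (non-plant cuvette?)")
  if (!inherits(state, "psychrometric_state"))
    cf_stop_input("`state` must be a psychrometric_state")
  molar_flow <- lpm_to_m3s(inlet_flow_lpm) * state$pressure_Pa /
    (R_GAS * state$temperature_K)  # mol air / s
  molar_flow * (co2_in_ppm - co2_out_ppm) / leaf_area_m2
}

#' Transpiration rate from inlet/outlet absolute humidity
#'
#' Mirror of the steady-state chamber formula for water vapor:
#' `E_s = F_in (h_out - h_in) / A_leaf`, reported in mmol m-2 s-1.
#'
#' @param h_in,h_out Absolute humidity at inlet / outlet, mol m-3.
#' @param inlet_flow_lpm Inlet flow, liters per minute.
#' @param leaf_area_m2 Enclosed leaf area, m2 (> 0).
#' @return Transpiration, mmol m-2 s-1 (positive = water release).
#' @export
transpiration_rate <- function(h_in, h_out, inlet_flow_lpm, leaf_area_m2) {
  if (!is.finite(leaf_area_m2) || leaf_area_m2 <= 0)
    cf_stop_invalid("`leaf_area_m2` must be > 0 (non-plant cuvette?)")
  lpm_to_m3s(inlet_flow_lpm) * (h_out - h_in) / leaf_area_m2 * 1e3
}

#' Remove the bare-soil contribution from plant-cuvette outlet values
#'
#' Plant cuvettes enclose the pot soil, so soil respiration and
#' evaporation contaminate the outlet CO2 and H2O signals. Reference
#' cuvettes holding pots with bare soil measure that contribution;
#' subtracting their excess over the inlet
#' (`corrected = plant_out - (soil_out - inlet)`) removes it from the
#' concentrations before any flux computation.
#'
#' Inputs may be numeric vectors on shared timestamps or
#' [conc_series()] objects; series are linearly interpolated onto the
#' plant series' timestamps.
#'
#' @param plant_out Plant-cuvette outlet series (`conc_series` or numeric).
#' @param soil_out Bare-soil reference outlet series.
#' @param inlet Inlet series (same channel).
#' @return Corrected outlet values: a `conc_series` if `plant_out` was
#'   one, otherwise a numeric vector.
#' @export
soil_reference_correct <- function(plant_out, soil_out, inlet) {
  if (inherits(plant_out, "conc_series")) {
    t <- plant_out$time_s
    soil_v <- align_onto(soil_out, t, "soil_out")
    in_v <- align_onto(inlet, t, "inlet")
    out <- plant_out$value - (soil_v - in_v)
    return(conc_series(plant_out$cuvette_id, plant_out$compound_id, t, out))
  }
  n <- length(plant_out)
  if ((is.numeric(soil_out) && length(soil_out) != n && length(soil_out) != 1L) ||
      (is.numeric(inlet) && length(inlet) != n && length(inlet) != 1L))
    cf_stop("soil/inlet vectors not alignable with plant_out",
            "cf_alignment_error")
  plant_out - (unclass_series(soil_out, n) - unclass_series(inlet, n))
}

align_onto <- function(x, t, what) {
  if (inherits(x, "conc_series")) {
    if (min(t) > max(x$time_s) || max(t) < min(x$time_s))
      cf_stop(sprintf("%s series does not overlap the plant series", what),
              "cf_alignment_error")
    if (length(x$time_s) == 1L) return(rep_len(x$value, length(t)))
    return(approx(x$time_s, x$value, xout = t, rule = 2)$y)
  }
  if (is.numeric(x)) {
    if (length(x) != length(t) && length(x) != 1L)
      cf_stop(sprintf("%s vector not alignable with plant series", what),
              "cf_alignment_error")
    return(rep_len(x, length(t)))
  }
  cf_stop_input(sprintf("cannot interpret %s", what))
}

unclass_series <- function(x, n) rep_len(x, n)

#' Evaporative-cooling temperature depression of cuvette air
#'
#' Steady-state energy balance: the enthalpy of vaporization drawn by
#' plant transpiration cools the through-flowing air by
#' `dT = E_s A H_v / (rho_air F_in c_p)`.
#' All factors are explicit inputs so published worked examples can be
#' reproduced with their stated density and heat capacity.
#'
#' @param transpiration_umol_m2_s Transpiration `E_s`, umol m-2 s-1
#'   (non-negative).
#' @param leaf_area_m2 Enclosed leaf area `A`, m2.
#' @param latent_heat_J_mol Molar enthalpy of vaporization `H_v`, J mol-1
#'   (see [latent_heat_vaporization()]).
#' @param air_density_kg_m3 Air density `rho_air`, kg m-3.
#' @param inlet_flow_lpm Cuvette inlet flow, liters per minute.
#' @param heat_capacity_J_kg_K Specific heat capacity `c_p`, J kg-1 K-1.
#' @return Temperature depression, K.
#' @examples
#' evaporative_delta_T(3, 0.5, 43990, 1.01, 10, 1106)  # ~0.35 K
#' @export
evaporative_delta_T <- function(transpiration_umol_m2_s, leaf_area_m2,
                                latent_heat_J_mol, air_density_kg_m3,
                                inlet_flow_lpm, heat_capacity_J_kg_K) {
  if (!is.finite(transpiration_umol_m2_s) || transpiration_umol_m2_s < 0)
    cf_stop_invalid("`transpiration_umol_m2_s` must be non-negative")
  pos <- c(leaf_area_m2, latent_heat_J_mol, air_density_kg_m3,
           inlet_flow_lpm, heat_capacity_J_kg_K)
  if (any(!is.finite(pos)) || any(pos <= 0))
    cf_stop_invalid("all energy-balance factors must be positive")
  (transpiration_umol_m2_s * 1e-6) * leaf_area_m2 * latent_heat_J_mol /
    (air_density_kg_m3 * lpm_to_m3s(inlet_flow_lpm) * heat_capacity_J_kg_K)
}
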