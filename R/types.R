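# Core domain types: cuvette configuration, emission profiles,
# per-cuvette concentration series, valve schedules.

CUVETTE_ROLES <- c("plant", "empty_background", "soil_reference")

#' Cuvette configuration
#'
#' Physical and role description of one cuvette: its enclosed air volume
#' `V` (liters), inlet flow `F_in` (liters per minute), role in the
#' experiment, and one-sided enclosed leaf area `A_leaf` (m2, zero for
#' non-plant roles).
#'
#' @param cuvette_id Identifier (character scalar).
#' @param volume_l Air volume in liters; must be positive.
#' @param inlet_flow_lpm Inlet flow in liters per minute; must be positive.
#' @param role One of `"plant"`, `"empty_background"`, `"soil_reference"`.
#' @param leaf_area_m2 Enclosed one-sided leaf area in m2. Must be
#'   positive for `role = "plant"` and zero otherwise.
#' @return An object of class `cuvette_config`.
#' @examples
#' cuvette_config("cuv01", 40, 6, "plant", leaf_area_m2 = 0.05)
#' @export
cuvette_config <- function(cuvette_id, volume_l, inlet_flow_lpm,
                           role = c("plant", "empty_background", "soil_reference"),
                           leaf_area_m2 = 0) {
  role <- match.arg(role)
  if (!is.numeric(volume_l) || length(volume_l) != 1L || !is.finite(volume_l) ||
      volume_l <= 0)
    cf_stop_invalid("`volume_l` must be a single positive number")
  if (!is.numeric(inlet_flow_lpm) || length(inlet_flow_lpm) != 1L ||
      !is.finite(inlet_flow_lpm) || inlet_flow_lpm <= 0)
    cf_stop_invalid("`inlet_flow_lpm` must be a single positive number")
  if (!is.numeric(leaf_area_m2) || length(leaf_area_m2) != 1L ||
      !is.finite(leaf_area_m2) || leaf_area_m2 < 0)
    cf_stop_invalid("`leaf_area_m2` must be a single non-negative number")
  if (role == "plant" && leaf_area_m2 <= 0)
    cf_stop_invalid("a plant cuvette needs `leaf_area_m2` > 0")
  if (role != "plant" && leaf_area_m2 > 0)
    cf_stop_invalid(sprintf("`leaf_area_m2` must be 0 for role '%s'", role))
  structure(
    list(cuvette_id = as.character(cuvette_id), volume_l = volume_l,
         inlet_flow_lpm = inlet_flow_lpm, role = role,
         leaf_area_m2 = leaf_area_m2),
    class = "cuvette_config"
  )
}

#' @export
print.cuvette_config <- function(x, ...) {
  cat(sprintf("<cuvette_config> %s: V = %g L, F_in = %g L/min, role = %s, A_leaf = %g m2\n",
              x$cuvette_id, x$volume_l, x$inlet_flow_lpm, x$role, x$leaf_area_m2))
  invisible(x)
}

#' Emission-rate profile E(t)
#'
#' A net emission-rate function of time for one compound,
#' in nmol m-2 s-1 of one-sided leaf area. Negative values denote net
#' uptake. Built-in shapes:
#' \describe{
#'   \item{constant}{`E(t) = rate`.}
#'   \item{step}{`rate0` before `t_step` seconds, `rate1` after.}
#'   \item{diurnal_sine}{half-sine over the light phase of a 24-h day
#'     (`peak * sin(pi * t_in_light / light_s)`), zero in the dark;
#'     non-negative by construction when `peak >= 0` and `floor >= 0`.
#'     `floor` adds a constant dark-phase rate (e.g. respiration when
#'     negative is explicitly allowed with `emission_only = FALSE`).}
#'   \item{custom}{any vectorized function `fun(t)`.}
#' }
#'
#' @param compound_id Identifier.
#' @param shape One of `"constant"`, `"step"`, `"diurnal_sine"`, `"custom"`.
#' @param rate Constant rate (shape `"constant"`).
#' @param rate0,rate1,t_step Step parameters (shape `"step"`).
#' @param peak Peak rate at mid-light (shape `"diurnal_sine"`).
#' @param light_s Length of the light phase in seconds (default 43200,
#'   a 12/12 photoperiod); the light phase starts at `t mod 86400 = 0`.
#' @param floor Dark-phase rate (shape `"diurnal_sine"`, default 0).
#' @param fun Vectorized function of time in seconds (shape `"custom"`).
#' @param emission_only If `TRUE` (default for `"diurnal_sine"`), negative
#'   configured rates are rejected at construction.
#' @return An object of class `emission_profile` with an `$evaluate`
#'   function mapping seconds to nmol m-2 s-1.
#' @examples
#' p <- emission_profile("methanol", "diurnal_sine", peak = 5)
#' p$evaluate(c(0, 21600, 43200, 64800)) # dawn, noon, dusk, midnight
#' @export
emission_profile <- function(compound_id,
                             shape = c("constant", "step", "diurnal_sine", "custom"),
                             rate = 0, rate0 = 0, rate1 = 0, t_step = 0,
                             peak = 0, light_s = 43200, floor = 0,
                             fun = NULL, emission_only = NULL) {
  shape <- match.arg(shape)
  evaluate <- switch(shape,
    constant = local({ r <- rate; function(t) rep_len(r, length(t)) }),
    step = local({
      r0 <- rate0; r1 <- rate1; ts <- t_step
      function(t) ifelse(t < ts, r0, r1)
    }),
    diurnal_sine = local({
      if (is.null(emission_only)) emission_only <- TRUE
      if (emission_only && (peak < 0 || floor < 0))
        cf_stop_invalid("diurnal_sine configured emission-only but peak/floor negative")
      pk <- peak; ls <- light_s; fl <- floor
      function(t) {
        tm <- t %% 86400
        ifelse(tm < ls, pk * sin(pi * tm / ls), fl)
      }
    }),
    custom = {
      if (!is.function(fun)) cf_stop_invalid("shape 'custom' needs `fun`")
      fun
    }
  )
  structure(list(compound_id = as.character(compound_id), shape = shape,
                 evaluate = evaluate),
            class = "emission_profile")
}

#' Timestamped concentration series for one cuvette and compound
#'
#' @param cuvette_id,compound_id Identifiers.
#' @param time_s Numeric timestamps in seconds, strictly increasing.
#' @param value Concentrations (nmol m-3 for VOC channels; the container
#'   is unit-agnostic and also carries CO2 ppm or H2O mol m-3 channels).
#' @return Object of class `conc_series`.
#' @export
conc_series <- function(cuvette_id, compound_id, time_s, value) {
  time_s <- as.numeric(time_s); value <- as.numeric(value)
  if (length(time_s) != length(value))
    cf_stop_input("`time_s` and `value` lengths differ")
  if (length(time_s) == 0L)
    cf_stop_input("empty concentration series")
  if (any(!is.finite(time_s)) || any(!is.finite(value)))
    cf_stop_input("concentration series must be finite")
  if (any(diff(time_s) <= 0))
    cf_stop_input("`time_s` must be strictly increasing")
  structure(list(cuvette_id = as.character(cuvette_id),
                 compound_id = as.character(compound_id),
                 time_s = time_s, value = value),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> %s / %s: %d samples, t in [%g, %g] s\n",
              x$cuvette_id, x$compound_id, length(x$time_s),
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' @export
as.data.frame.conc_series <- function(x, ...) {
  data.frame(cuvette_id = x$cuvette_id, compound_id = x$compound_id,
             time_s = x$time_s, value = x$value)
}

# coerce numeric scalar / conc_series to an interpolating function over
# `grid`; series must cover the grid unless clip = TRUE
series_fun <- function(x, grid, what = "inlet", clip = FALSE) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    v <- x
    return(function(t) rep_len(v, length(t)))
  }
  if (inherits(x, "conc_series")) {
    if (!clip && (min(grid) < min(x$time_s) - 1e-9 ||
                  max(grid) > max(x$time_s) + 1e-9))
      cf_stop_input(sprintf(
        "%s series [%g, %g] s does not cover the requested grid [%g, %g] s",
        what, min(x$time_s), max(x$time_s), min(grid), max(grid)))
    if (length(x$time_s) == 1L) {
      v <- x$value
      return(function(t) rep_len(v, length(t)))
    }
    ts <- x$time_s; vs <- x$value
    return(function(t) approx(ts, vs, xout = t, rule = 2)$y)
  }
  cf_stop_input(sprintf("cannot interpret %s input of class '%s'",
                        what, paste(class(x), collapse = "/")))
}

#' Valve-multiplexing schedule
#'
#' Downstream analyzers sample one cuvette at a time; 2-way valves switch
#' in fixed dwell intervals (typically 300 s). Records acquired within
#' the tubing gas-exchange lag after each switch are discarded.
#'
#' @param cuvette_order Character vector of unique cuvette ids, cycled in
#'   this order.
#' @param dwell_s Seconds each cuvette stays selected (default 300).
#' @param lag_s Seconds discarded after each valve switch (default 30;
#'   instrument tubing dependent).
#' @param start_time_s Time of the first valve switch (default 0); used
#'   when a log lacks an `active_cuvette` annotation.
#' @return Object of class `valve_schedule`.
#' @export
valve_schedule <- function(cuvette_order, dwell_s = 300, lag_s = 30,
                           start_time_s = 0) {
  cuvette_order <- as.character(cuvette_order)
  if (length(cuvette_order) == 0L)
    cf_stop_invalid("`cuvette_order` must be non-empty")
  if (anyDuplicated(cuvette_order))
    cf_stop_invalid("`cuvette_order` ids must be unique")
  if (!(dwell_s > lag_s) || lag_s < 0)
    cf_stop_invalid("need dwell_s > lag_s >= 0")
  structure(list(cuvette_order = cuvette_order, dwell_s = dwell_s,
                 lag_s = lag_s, start_time_s = start_time_s),
            class = "valve_schedule")
}

#' @export
print.valve_schedule <- function(x, ...) {
  cat(sprintf("<valve_schedule> %d cuvettes, dwell %g s, lag %g s (cycle %g s)\n",
              length(x$cuvette_order), x$dwell_s, x$lag_s,
              length(x$cuvette_order) * x$dwell_s))
  invisible(x)
}

#' Psychrometric state of moist air
#'
#' @param temperature_K Air temperature in kelvin.
#' @param pressure_Pa Total air pressure in pascal (default 96000 Pa, a
#'   typical phytotron-altitude operating pressure).
#' @param relative_humidity Fraction in \[0, 1\].
#' @return Object of class `psychrometric_state`.
#' @export
psychrometric_state <- function(temperature_K, pressure_Pa = 96000,
                                relative_humidity = 0) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    cf_stop_invalid("`temperature_K` must be positive")
  if (!is.finite(pressure_Pa) || pressure_Pa <= 0)
    cf_stop_invalid("`pressure_Pa` must be positive")
  if (!is.finite(relative_humidity) || relative_humidity < 0 ||
      relative_humidity > 1)
    cf_stop_invalid("`relative_humidity` must be in [0, 1]")
  structure(list(temperature_K = temperature_K, pressure_Pa = pressure_Pa,
                 relative_humidity = relative_humidity),
            class = "psychrometric_state")
}
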