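# Well-mixed flow-through cuvette model.
#
# Mass balance for compound i in a cuvette of volume V (m3) flushed at
# F (m3/s), with net emission E(t) (nmol m-2 s-1) over leaf area A (m2),
# assuming F_out = F_in and instantaneous turbulent mixing:
#
#   dc/dt = E(t) * A / V + (F/V) * (c_in(t) - c(t))
#
# tau = V/F is the characteristic air-exchange time constant; 5*tau
# corresponds to > 99 % air exchange. At steady state the balance
# inverts to the classic chamber formula E = (F/A) * (c_out - c_in).

#' Cuvette air-exchange time constant
#'
#' `tau = V / F_in`: the e-folding time of air replacement in a
#' well-mixed flow-through chamber. With a 40-L cuvette at
#' 10 / 15 L min-1, 5 tau (> 99 % exchange) is 20 / 13.3 min.
#'
#' @param volume_l Cuvette air volume, liters.
#' @param inlet_flow_lpm Inlet flow, liters per minute.
#' @return Time constant in minutes.
#' @examples
#' time_constant(40, 10)        # 4 min, so 5 tau = 20 min
#' 5 * time_constant(40, 15)    # 13.33 min
#' @export
time_constant <- function(volume_l, inlet_flow_lpm) {
  if (any(!is.finite(volume_l)) || any(volume_l <= 0))
    cf_stop_invalid("`volume_l` must be positive")
  if (any(!is.finite(inlet_flow_lpm)) || any(inlet_flow_lpm <= 0))
    cf_stop_invalid("`inlet_flow_lpm` must be positive")
  volume_l / inlet_flow_lpm
}

#' Fraction of cuvette air replaced after a given time
#'
#' For a well-mixed chamber the replaced-air fraction after `elapsed`
#' seconds is `1 - exp(-elapsed / tau)`; at 5 tau it exceeds 99 %.
#'
#' @param elapsed_s Elapsed time, seconds (non-negative).
#' @param tau_s Time constant, seconds (positive).
#' @return Fraction in \[0, 1).
#' @examples
#' exchange_fraction(5 * 240, 240)  # 0.9933
#' @export
exchange_fraction <- function(elapsed_s, tau_s) {
  if (any(!is.finite(elapsed_s)) || any(elapsed_s < 0))
    cf_stop_invalid("`elapsed_s` must be non-negative")
  if (any(!is.finite(tau_s)) || any(tau_s <= 0))
    cf_stop_invalid("`tau_s` must be positive")
  1 - exp(-elapsed_s / tau_s)
}

# ---------------------------------------------------------------------
# Adaptive Dormand-Prince 5(4) for the scalar chamber ODE.
# dy/dt = f(t, y); steps never cross a requested output time, solution
# recorded exactly at `times`. rtol/atol control the embedded-error
# step size. Sufficient here: the system is linear and non-stiff at
# realistic tau (minutes).

rk45_scalar <- function(f, y0, times, rtol = 1e-8, atol = 1e-12) {
  # Butcher tableau (Dormand & Prince 1980)
  a21 <- 1/5
  a31 <- 3/40;        a32 <- 9/40
  a41 <- 44/45;       a42 <- -56/15;      a43 <- 32/9
  a51 <- 19372/6561;  a52 <- -25360/2187; a53 <- 64448/6561; a54 <- -212/729
  a61 <- 9017/3168;   a62 <- -355/33;     a63 <- 46732/5247
  a64 <- 49/176;      a65 <- -5103/18656
  b1 <- 35/384; b3 <- 500/1113; b4 <- 125/192; b5 <- -2187/6784; b6 <- 11/84
  e1 <- b1 - 5179/57600; e3 <- b3 - 7571/16695; e4 <- b4 - 393/640
  e5 <- b5 + 92097/339200; e6 <- b6 - 187/2100; e7 <- -1/40
  c2 <- 1/5; c3 <- 3/10; c4 <- 4/5; c5 <- 8/9

  n <- length(times)
  out <- numeric(n)
  t <- times[1L]; y <- y0
  out[1L] <- y
  if (n == 1L) return(out)
  h <- min(diff(times)[1L], (times[n] - t) / 10)
  k1 <- f(t, y)
  for (i in 2L:n) {
    t_end <- times[i]
    while (t < t_end - 1e-12 * max(1, abs(t_end))) {
      h <- min(h, t_end - t)
      k2 <- f(t + c2 * h, y + h * a21 * k1)
      k3 <- f(t + c3 * h, y + h * (a31 * k1 + a32 * k2))
      k4 <- f(t + c4 * h, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
      k5 <- f(t + c5 * h, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
      k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5))
      y5 <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
      k7 <- f(t + h, y5)  # FSAL
      err <- h * abs(e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
      sc <- atol + rtol * max(abs(y), abs(y5))
      if (err <= sc || h <= 1e-10 * max(1, abs(t))) {
        t <- t + h; y <- y5; k1 <- k7
        fac <- if (err > 0) 0.9 * (sc / err)^0.2 else 5
        h <- h * min(5, max(0.2, fac))
      } else {
        h <- h * max(0.2, 0.9 * (sc / err)^0.2)
      }
    }
    out[i] <- y
  }
  out
}

#' Simulate compound concentration in a flow-through cuvette
#'
#' Integrates the well-mixed chamber mass balance
#' `dc/dt = E(t) A_leaf / V + (F_in / V) (c_in(t) - c)` with an adaptive
#' Runge-Kutta 5(4) scheme (relative tolerance 1e-8 by default) and
#' returns the outlet concentration sampled on `time_grid`. For constant
#' `E` and `c_in` the solution converges to `c_in + E A_leaf / F_in`.
#'
#' @param config A [cuvette_config()].
#' @param emission An [emission_profile()] (nmol m-2 s-1), or `NULL` for
#'   no source. Ignored (treated as zero source) when the cuvette has no
#'   leaf area.
#' @param inlet Inlet concentration: a single number, a `conc_series`
#'   covering `time_grid` (linearly interpolated), or a function of time.
#' @param time_grid Strictly increasing output times, seconds.
#' @param initial_concentration Concentration at `time_grid[1]`
#'   (nmol m-3, default 0).
#' @param rtol Relative integration tolerance.
#' @param source_fun Advanced: an explicit volumetric source term
#'   S(t) in concentration units per second that overrides
#'   `emission` (used internally for CO2/H2O channels whose source is
#'   not a leaf-area emission).
#' @return A [conc_series()] on `time_grid`.
#' @examples
#' cfg <- cuvette_config("c1", 40, 10, "plant", leaf_area_m2 = 0.1)
#' em  <- emission_profile("voc", "constant", rate = 2)
#' s <- simulate_concentration(cfg, em, inlet = 0,
#'                             time_grid = seq(0, 7200, by = 30))
#' tail(s$value, 1)  # ~ E * A / F = 2 * 0.1 / (10/6e4) = 1200 nmol m-3
#' @export
simulate_concentration <- function(config, emission, inlet, time_grid,
                                   initial_concentration = 0, rtol = 1e-8,
                                   source_fun = NULL) {
  if (!inherits(config, "cuvette_config"))
    cf_stop_input("`config` must be a cuvette_config")
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 2L || any(diff(time_grid) <= 0))
    cf_stop_input("`time_grid` must be strictly increasing with >= 2 points")
  V <- l_to_m3(config$volume_l)
  Fm <- lpm_to_m3s(config$inlet_flow_lpm)
  k <- Fm / V
  cin <- series_fun(inlet, time_grid, what = "inlet")
  if (is.null(source_fun)) {
    if (is.null(emission) || config$leaf_area_m2 == 0) {
      src <- function(t) 0
    } else {
      if (!inherits(emission, "emission_profile"))
        cf_stop_input("`emission` must be an emission_profile or NULL")
      ev <- emission$evaluate
      AoverV <- config$leaf_area_m2 / V
      src <- function(t) ev(t) * AoverV
    }
  } else {
    src <- source_fun
  }
  f <- function(t, y) src(t) + k * (cin(t) - y)
  vals <- rk45_scalar(f, initial_concentration, time_grid, rtol = rtol)
  compound <- if (inherits(emission, "emission_profile")) emission$compound_id else "compound"
  conc_series(config$cuvette_id, compound, time_grid, vals)
}

#' Steady-state emission rate from an inlet/outlet concentration gradient
#'
#' The classic flow-through chamber formula
#' `E = (F_in / A_leaf) * (c_out - c_in)` with the flow converted to
#' m3 s-1; valid where `dc/dt = 0`. A negative result signals net uptake.
#'
#' @param inlet_flow_lpm Inlet flow, liters per minute.
#' @param leaf_area_m2 Enclosed one-sided leaf area, m2 (> 0).
#' @param c_out,c_in Outlet / inlet concentrations, nmol m-3 (vectors
#'   allowed, recycled).
#' @return Emission rate(s), nmol m-2 s-1.
#' @examples
#' steady_state_emission(6, 0.1, c_out = 1, c_in = 0)  # 1e-3 nmol m-2 s-1
#' @export
steady_state_emission <- function(inlet_flow_lpm, leaf_area_m2, c_out, c_in = 0) {
  if (!is.finite(leaf_area_m2) || leaf_area_m2 <= 0)
    cf_stop_invalid("`leaf_area_m2` must be > 0 (non-plant cuvette?)")
  if (!is.finite(inlet_flow_lpm) || inlet_flow_lpm <= 0)
    cf_stop_invalid("`inlet_flow_lpm` must be > 0")
  lpm_to_m3s(inlet_flow_lpm) / leaf_area_m2 * (c_out - c_in)
}

# second-order derivative on a (possibly non-uniform) grid:
# 3-point central in the interior, one-sided 2-point at the boundaries
grid_derivative <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  if (n < 2L) return(d)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n]  <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    h1 <- t[i] - t[i - 1L]
    h2 <- t[i + 1L] - t[i]
    d[i] <- (-h2 / (h1 * (h1 + h2))) * y[i - 1L] +
      ((h2 - h1) / (h1 * h2)) * y[i] +
      (h1 / (h2 * (h1 + h2))) * y[i + 1L]
  }
  d
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Dynamic (mass-balance) emission rate from a concentration time series
#'
#' Inverts the chamber mass balance without assuming steady state:
#' `E(t) = (V dc_out/dt + F_in (c_out - c_in)) / A_leaf`, with the
#' derivative estimated by second-order central differences (one-sided at
#' the boundaries). Reduces exactly to [steady_state_emission()] wherever
#' `dc/dt = 0`.
#'
#' @param outlet A `conc_series` with at least 3 samples.
#' @param inlet Inlet concentration (number, `conc_series`, or function);
#'   linearly interpolated onto the outlet timestamps.
#' @param config A [cuvette_config()] (plant role: `leaf_area_m2 > 0`).
#' @param smooth_window Optional odd moving-average window (samples)
#'   applied to the derivative estimate; default 0 = no smoothing.
#' @return A `conc_series`-shaped object whose `value` is the emission
#'   rate in nmol m-2 s-1 at the outlet timestamps.
#' @export
dynamic_emission <- function(outlet, inlet, config, smooth_window = 0L) {
  if (!inherits(outlet, "conc_series"))
    cf_stop_input("`outlet` must be a conc_series")
  if (length(outlet$time_s) < 3L)
    cf_stop(sprintf("dynamic_emission needs >= 3 samples, got %d",
                    length(outlet$time_s)), "cf_insufficient_data")
  if (!inherits(config, "cuvette_config"))
    cf_stop_input("`config` must be a cuvette_config")
  if (config$leaf_area_m2 <= 0)
    cf_stop_invalid("`leaf_area_m2` must be > 0 (non-plant cuvette?)")
  V <- l_to_m3(config$volume_l)
  Fm <- lpm_to_m3s(config$inlet_flow_lpm)
  cin <- series_fun(inlet, outlet$time_s, what = "inlet", clip = TRUE)(outlet$time_s)
  dcdt <- grid_derivative(outlet$time_s, outlet$value)
  if (smooth_window > 1L) dcdt <- moving_average(dcdt, as.integer(smooth_window))
  E <- (V * dcdt + Fm * (outlet$value - cin)) / config$leaf_area_m2
  conc_series(outlet$cuvette_id, outlet$compound_id, outlet$time_s, E)
}
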