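# Synthetic experiment generator: complete multiplexed cuvette
# experiments with known ground truth, so every pipeline stage can be
# tested end-to-end without instrument data.
#
# The stated world mirrors the platform's case-study conditions:
# 24 cuvettes (plant / empty-background / bare-soil roles), ~40 L
# volume, 6 L/min inlet flow, 300 s valve dwell, a 12/12-h photoperiod
# with half-sine diurnal emission over the light phase, constant soil
# efflux in soil-containing cuvettes, a slow cubic contaminant drift in
# the supply air, and i.i.d. Gaussian sensor noise per channel.

#' Specification of a synthetic cuvette experiment
#'
#' Defaults emulate a 24-cuvette screening run: 18 plant cuvettes,
#' 3 empty background cuvettes, 3 bare-soil reference cuvettes, 40-L
#' cuvettes at 6 L/min, 300-s valve dwell with 30-s lag, 12/12-h
#' photoperiod, one VOC channel with a 5 nmol m-2 s-1 mid-light peak,
#' assimilation peaking at 10 umol m-2 s-1 and transpiration at
#' 1 mmol m-2 s-1, soil efflux of 0.05 umol CO2 s-1 and 1e-5 mol
#' H2O s-1 per pot, and a slow cubic contaminant drift on the VOC
#' channel.
#'
#' @param n_plant,n_background,n_soil Cuvette counts per role
#'   (default 18 / 3 / 3 = 24).
#' @param duration_days Experiment length (default 1).
#' @param dwell_s,lag_s Valve schedule (defaults 300 / 30 s).
#' @param record_interval_s Sensor record spacing within a dwell window
#'   (default 10 s).
#' @param volume_l,inlet_flow_lpm,leaf_area_m2 Cuvette physics
#'   (defaults 40 L, 6 L/min, 0.05 m2 per plant).
#' @param voc_profiles Named list of [emission_profile()]s applied to
#'   every plant cuvette; names are the VOC channel ids. Default: one
#'   channel `"voc1"`, diurnal half-sine, peak 5 nmol m-2 s-1.
#' @param assimilation_peak_umol Mid-light net assimilation peak,
#'   umol m-2 s-1 (half-sine over the light phase; default 10).
#' @param transpiration_peak_mmol Mid-light transpiration peak,
#'   mmol m-2 s-1 (default 1).
#' @param soil_co2_umol_s,soil_h2o_mol_s Constant soil efflux per pot,
#'   present in plant and soil-reference cuvettes (defaults 0.05 umol/s
#'   CO2, 1e-5 mol/s H2O).
#' @param inlet_co2_ppm Supply-air CO2 (default 400 ppm).
#' @param temperature_K,pressure_Pa,inlet_rh Cuvette air state
#'   (defaults 298.15 K, 96000 Pa, RH 0.5).
#' @param drift_coef Cubic polynomial coefficients (nmol m-3 per day^k,
#'   k = 0..3) of the VOC supply-air contaminant drift,
#'   default `c(200, 120, -40, 8)`.
#' @param noise_sd Named per-channel Gaussian sigma; entries `voc`
#'   (nmol m-3, applied to every VOC channel), `co2_ppm`, `h2o_molm3`.
#'   Default all zero (noiseless).
#' @param light_s Light-phase length, seconds (default 43200).
#' @param seed Integer RNG seed; a fixed seed makes the generated
#'   experiment byte-identical.
#' @return Object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_plant = 18, n_background = 3, n_soil = 3,
                            duration_days = 1, dwell_s = 300, lag_s = 30,
                            record_interval_s = 10,
                            volume_l = 40, inlet_flow_lpm = 6,
                            leaf_area_m2 = 0.05,
                            voc_profiles = NULL,
                            assimilation_peak_umol = 10,
                            transpiration_peak_mmol = 1,
                            soil_co2_umol_s = 0.05, soil_h2o_mol_s = 1e-5,
                            inlet_co2_ppm = 400,
                            temperature_K = 298.15, pressure_Pa = 96000,
                            inlet_rh = 0.5,
                            drift_coef = c(200, 120, -40, 8),
                            noise_sd = c(voc = 0, co2_ppm = 0, h2o_molm3 = 0),
                            light_s = 43200, seed = 1L) {
  if (n_plant < 0 || n_background < 0 || n_soil < 0 ||
      n_plant + n_background + n_soil < 1)
    cf_stop_invalid("need at least one cuvette")
  if (is.null(voc_profiles))
    voc_profiles <- list(voc1 = emission_profile("voc1", "diurnal_sine",
                                                 peak = 5, light_s = light_s))
  if (is.null(names(voc_profiles)) || any(!nzchar(names(voc_profiles))))
    cf_stop_invalid("`voc_profiles` must be a named list (names = channel ids)")
  nd <- c(voc = 0, co2_ppm = 0, h2o_molm3 = 0)
  nd[names(noise_sd)] <- noise_sd
  structure(list(
    n_plant = n_plant, n_background = n_background, n_soil = n_soil,
    duration_days = duration_days, dwell_s = dwell_s, lag_s = lag_s,
    record_interval_s = record_interval_s,
    volume_l = volume_l, inlet_flow_lpm = inlet_flow_lpm,
    leaf_area_m2 = leaf_area_m2, voc_profiles = voc_profiles,
    assimilation_peak_umol = assimilation_peak_umol,
    transpiration_peak_mmol = transpiration_peak_mmol,
    soil_co2_umol_s = soil_co2_umol_s, soil_h2o_mol_s = soil_h2o_mol_s,
    inlet_co2_ppm = inlet_co2_ppm, temperature_K = temperature_K,
    pressure_Pa = pressure_Pa, inlet_rh = inlet_rh,
    drift_coef = drift_coef, noise_sd = nd, light_s = light_s,
    seed = as.integer(seed)
  ), class = "experiment_spec")
}

# cubic contaminant drift, nmol m-3, t in seconds
drift_fun <- function(coef) {
  function(t) {
    d <- t / 86400
    coef[1] + coef[2] * d + coef[3] * d^2 + coef[4] * d^3
  }
}

# diurnal half-sine over the light phase
half_sine <- function(peak, light_s, floor = 0) {
  function(t) {
    tm <- t %% 86400
    ifelse(tm < light_s, peak * sin(pi * tm / light_s), floor)
  }
}

# cuvette roles and configs implied by a spec
spec_configs <- function(spec) {
  roles <- c(rep("plant", spec$n_plant),
             rep("empty_background", spec$n_background),
             rep("soil_reference", spec$n_soil))
  ids <- sprintf("cuv%02d", seq_along(roles))
  configs <- lapply(seq_along(roles), function(i)
    cuvette_config(ids[i], spec$volume_l, spec$inlet_flow_lpm, roles[i],
                   if (roles[i] == "plant") spec$leaf_area_m2 else 0))
  names(configs) <- ids
  configs
}

#' Generate a synthetic multiplexed cuvette experiment
#'
#' Simulates every cuvette's outlet concentrations with the forward
#' chamber model ([simulate_concentration()]'s integrator), interleaves
#' them according to the valve schedule, adds per-channel Gaussian
#' sensor noise, and returns the raw log together with the inlet
#' analyzer series and full ground truth.
#'
#' Channels: one per VOC profile (nmol m-3), `co2_ppm` (umol mol-1) and
#' `h2o_molm3` (mol m-3). Soil efflux acts in plant and soil-reference
#' cuvettes; the supply-air contaminant drift acts on every cuvette's
#' VOC channels; assimilation/transpiration act in plant cuvettes only.
#'
#' @param spec An [experiment_spec()].
#' @return A list with elements `log` (data.frame: `time_s`,
#'   `active_cuvette`, `channel`, `value`), `inlet` (data.frame:
#'   `time_s`, `channel`, `value`; CO2 and H2O channels), `truth`
#'   (data.frame of configured rates at every plant-cuvette record
#'   time), `truth_funs` (list of the underlying rate functions),
#'   `configs`, `schedule`, and `spec`.
#' @export
generate_experiment <- function(spec) {
  if (!inherits(spec, "experiment_spec"))
    cf_stop_input("`spec` must be an experiment_spec")
  configs <- spec_configs(spec)
  ids <- names(configs)
  schedule <- valve_schedule(ids, spec$dwell_s, spec$lag_s)
  n_cuv <- length(ids)
  cycle_s <- n_cuv * spec$dwell_s
  duration_s <- spec$duration_days * 86400
  n_cycles <- max(1L, floor(duration_s / cycle_s))

  V_m3 <- l_to_m3(spec$volume_l)
  tau_s <- 60 * time_constant(spec$volume_l, spec$inlet_flow_lpm)
  n_air <- spec$pressure_Pa * V_m3 / (R_GAS * spec$temperature_K)  # mol

  inlet_h2o <- absolute_humidity(psychrometric_state(
    spec$temperature_K, spec$pressure_Pa, spec$inlet_rh))
  drift <- drift_fun(spec$drift_coef)
  assim <- half_sine(spec$assimilation_peak_umol, spec$light_s)
  transp <- half_sine(spec$transpiration_peak_mmol, spec$light_s)

  # per-dwell record offsets within a window
  offs <- seq(0, spec$dwell_s - spec$record_interval_s,
              by = spec$record_interval_s)

  sim_one <- function(cfg, source_fn, cin) {
    # record times of this cuvette across all its dwell windows
    slot <- match(cfg$cuvette_id, ids) - 1L
    starts <- slot * spec$dwell_s + (seq_len(n_cycles) - 1L) * cycle_s
    times <- as.vector(outer(offs, starts, `+`))
    times <- sort(times)
    cin_f <- series_fun(cin, times)
    # start in steady state for the source active just before t = 0
    c0 <- cin_f(times[1]) + source_fn(times[1]) * tau_s
    sim <- simulate_concentration(cfg, emission = NULL, inlet = cin,
                                  time_grid = times,
                                  initial_concentration = c0,
                                  source_fun = source_fn)
    sim
  }

  with_seed(spec$seed, {
    rows <- vector("list", 3L * n_cuv)
    ri <- 0L
    for (cfg in configs) {
      is_plant <- cfg$role == "plant"
      has_soil <- cfg$role %in% c("plant", "soil_reference")
      A <- cfg$leaf_area_m2
      # VOC channels
      for (ch in names(spec$voc_profiles)) {
        prof <- spec$voc_profiles[[ch]]
        src <- if (is_plant) {
          ev <- prof$evaluate
          function(t) ev(t) * A / V_m3
        } else function(t) rep_len(0, length(t))
        sim <- sim_one(cfg, src, drift)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(time_s = sim$time_s,
                                 active_cuvette = cfg$cuvette_id,
                                 channel = ch, value = sim$value)
      }
      # CO2 (ppm): assimilation sink + soil source, in mixing-ratio units
      src_co2 <- local({
        soil <- if (has_soil) spec$soil_co2_umol_s else 0
        plant <- is_plant; Al <- A
        function(t) (soil - (if (plant) assim(t) * Al else 0)) / n_air
      })
      sim <- sim_one(cfg, src_co2, spec$inlet_co2_ppm)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(time_s = sim$time_s,
                               active_cuvette = cfg$cuvette_id,
                               channel = "co2_ppm", value = sim$value)
      # H2O (mol m-3): transpiration + soil evaporation
      src_h2o <- local({
        soil <- if (has_soil) spec$soil_h2o_mol_s else 0
        plant <- is_plant; Al <- A
        function(t) (soil + (if (plant) transp(t) * 1e-3 * Al else 0)) / V_m3
      })
      sim <- sim_one(cfg, src_h2o, inlet_h2o)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(time_s = sim$time_s,
                               active_cuvette = cfg$cuvette_id,
                               channel = "h2o_molm3", value = sim$value)
    }
    log <- do.call(rbind, rows[seq_len(ri)])
    log <- log[order(log$time_s, log$channel), , drop = FALSE]
    rownames(log) <- NULL

    # inlet analyzer: 60-s cadence over the whole experiment
    t_in <- seq(0, n_cycles * cycle_s, by = 60)
    inlet <- rbind(
      data.frame(time_s = t_in, channel = "co2_ppm",
                 value = rep_len(spec$inlet_co2_ppm, length(t_in))),
      data.frame(time_s = t_in, channel = "h2o_molm3",
                 value = rep_len(inlet_h2o, length(t_in)))
    )

    # sensor noise, one pseudo-random stream
    sd_of <- function(ch) {
      if (ch %in% names(spec$noise_sd)) spec$noise_sd[[ch]] else spec$noise_sd[["voc"]]
    }
    for (ch in unique(log$channel)) {
      s <- sd_of(ch)
      if (s > 0) {
        i <- log$channel == ch
        log$value[i] <- log$value[i] + rnorm(sum(i), 0, s)
      }
    }
    for (ch in unique(inlet$channel)) {
      s <- sd_of(ch)
      if (s > 0) {
        i <- inlet$channel == ch
        inlet$value[i] <- inlet$value[i] + rnorm(sum(i), 0, s)
      }
    }

    # ground truth at every plant-cuvette record time
    plant_ids <- ids[vapply(configs, function(cf) cf$role == "plant", logical(1))]
    truth <- NULL
    if (length(plant_ids)) {
      tr <- lapply(plant_ids, function(cid) {
        slot <- match(cid, ids) - 1L
        starts <- slot * spec$dwell_s + (seq_len(n_cycles) - 1L) * cycle_s
        times <- sort(as.vector(outer(offs, starts, `+`)))
        out <- data.frame(cuvette_id = cid, time_s = times,
                          assimilation_umol_m2_s = assim(times),
                          transpiration_mmol_m2_s = transp(times))
        for (ch in names(spec$voc_profiles))
          out[[paste0("emission_", ch, "_nmol_m2_s")]] <-
            spec$voc_profiles[[ch]]$evaluate(times)
        out
      })
      truth <- do.call(rbind, tr)
      rownames(truth) <- NULL
    }

    truth_funs <- c(
      list(assimilation = assim, transpiration = transp, voc_inlet_drift = drift),
      setNames(lapply(spec$voc_profiles, `[[`, "evaluate"),
               paste0("emission_", names(spec$voc_profiles)))
    )

    list(log = log, inlet = inlet, truth = truth, truth_funs = truth_funs,
         configs = configs, schedule = schedule, spec = spec)
  })
}

#' Generate a synthetic plant image with a known green-pixel count
#'
#' Uniform blue background with exactly `n_green` pure-green pixels at
#' seeded-random positions; the truth count is returned alongside, so
#' [count_plant_pixels()] can be tested by construction.
#'
#' @param n_green Number of green pixels (<= width * height).
#' @param width,height Image size in pixels (defaults 64 x 64).
#' @param seed Integer seed (default 1).
#' @return List with `image` (RGB array in \[0, 1\]) and `n_green`.
#' @export
generate_plant_image <- function(n_green, width = 64, height = 64, seed = 1L) {
  if (n_green < 0 || n_green > width * height)
    cf_stop_invalid("`n_green` must be between 0 and width * height")
  with_seed(seed, {
    img <- array(0, c(height, width, 3))
    img[, , 1] <- 0.10; img[, , 2] <- 0.15; img[, , 3] <- 0.85  # blue
    if (n_green > 0) {
      pos <- sample.int(width * height, n_green)
      r <- ((pos - 1L) %% height) + 1L
      c <- ((pos - 1L) %/% height) + 1L
      for (k in seq_len(n_green)) {
        img[r[k], c[k], ] <- c(0.12, 0.85, 0.18)  # hue ~125 deg, sat ~0.86
      }
    }
    list(image = img, n_green = as.integer(n_green))
  })
}
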