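# Psychrometrics, CO2/H2O fluxes, soil correction, energy balance.
# Frozen numeric expectations were computed from the closed forms
# stated in the docs (Magnus correlation, two-component ideal gas,
# R T^2 dln(es)/dT) evaluated independently.

test_that("saturation vapor pressure matches the Magnus correlation", {
  expect_equal(saturation_vapor_pressure(273.15), 610.94, tolerance = 1e-9)
  expect_equal(saturation_vapor_pressure(298.15), 3161.736, tolerance = 1e-4)
  T_grid <- seq(240, 330, by = 5)
  expect_true(all(diff(saturation_vapor_pressure(T_grid)) > 0))
  expect_error(saturation_vapor_pressure(200), class = "cf_invalid_parameter")
})

test_that("absolute humidity is ideal-gas vapor and linear in RH", {
  expect_equal(absolute_humidity(psychrometric_state(298.15, 96000, 0)), 0)
  h1 <- absolute_humidity(psychrometric_state(298.15, 96000, 0.4))
  h2 <- absolute_humidity(psychrometric_state(298.15, 96000, 0.8))
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
  expect_equal(absolute_humidity(psychrometric_state(298.15, 96000, 1)),
               3161.736 / (8.314462618 * 298.15), tolerance = 1e-4)
})

test_that("air density: dry reference value and humid-air property", {
  expect_equal(air_density(psychrometric_state(273.15, 101325, 0)),
               1.292248, tolerance = 1e-5)
  dry <- air_density(psychrometric_state(298.15, 96000, 0))
  humid <- air_density(psychrometric_state(298.15, 96000, 0.8))
  expect_lt(humid, dry)
  expect_equal(humid, 1.110503, tolerance = 1e-5)
})

test_that("latent heat of vaporization from Clausius-Clapeyron", {
  expect_equal(latent_heat_vaporization(298.15), 43990,
               tolerance = 0.005)                       # within 0.5%
  expect_equal(latent_heat_vaporization(373.15), 42142.4, tolerance = 1e-4)
  T_grid <- seq(273.15, 373.15, by = 10)
  expect_true(all(diff(latent_heat_vaporization(T_grid)) < 0))
})

test_that("net_co2_assimilation: molar-flow conversion and antisymmetry", {
  st <- psychrometric_state(298.15, 96000)
  expect_equal(net_co2_assimilation(400, 400, 6, 0.05, st), 0)
  expect_equal(net_co2_assimilation(400, 390, 6, 0.05, st),
               1e-4 * 96000 / (8.314462618 * 298.15) * 10 / 0.05,
               tolerance = 1e-12)
  a <- net_co2_assimilation(400, 380, 10, 0.1, st)
  b <- net_co2_assimilation(380, 400, 10, 0.1, st)
  expect_equal(a, -b)
  expect_equal(net_co2_assimilation(400, 380, 10, 0.1, st),
               2 * net_co2_assimilation(400, 390, 10, 0.1, st),
               tolerance = 1e-12)                        # linear in delta
  expect_error(net_co2_assimilation(400, 390, 6, 0, st),
               class = "cf_invalid_parameter")
})

test_that("transpiration_rate mirrors the chamber formula for water", {
  expect_equal(transpiration_rate(1, 1, 10, 0.5), 0)
  expect_equal(transpiration_rate(0, 0.1, 10, 0.5),
               (10 / 6e4) * 0.1 / 0.5 * 1e3, tolerance = 1e-12)
  expect_equal(transpiration_rate(0.1, 0, 10, 0.5),
               -transpiration_rate(0, 0.1, 10, 0.5))
})

test_that("soil_reference_correct removes the soil contribution", {
  t <- seq(0, 100, 10)
  inlet <- rep(400, length(t))
  # inert soil: soil outlet equals inlet -> no change
  plant <- fix_series(t, 350 + t / 10, comp = "co2_ppm")
  corr <- soil_reference_correct(plant, fix_series(t, inlet, id = "s"),
                                 fix_series(t, inlet, id = "i"))
  expect_equal(corr$value, plant$value)
  # soil adds constant s -> corrected outlet drops by s, so computed
  # assimilation rises by molar_flow * s / A_leaf
  s_off <- 12
  corr2 <- soil_reference_correct(plant,
                                  fix_series(t, inlet + s_off, id = "s"),
                                  fix_series(t, inlet, id = "i"))
  expect_equal(corr2$value, plant$value - s_off)
  st <- psychrometric_state(298.15, 96000)
  dA <- net_co2_assimilation(400, corr2$value[1], 6, 0.05, st) -
    net_co2_assimilation(400, plant$value[1], 6, 0.05, st)
  molar_flow <- 1e-4 * 96000 / (8.314462618 * 298.15)
  expect_equal(dA, molar_flow * s_off / 0.05, tolerance = 1e-12)
  # misalignment rejected
  expect_error(soil_reference_correct(plant,
                                      fix_series(t + 1e6, inlet, id = "s"),
                                      fix_series(t, inlet, id = "i")),
               class = "cf_alignment_error")
})

test_that("evaporative delta-T reproduces the energy-balance scaling", {
  dT10 <- evaporative_delta_T(3, 0.5, 43990, 1.01, 10, 1106)
  dT20 <- evaporative_delta_T(3, 0.5, 43990, 1.01, 20, 1106)
  expect_equal(dT20, dT10 / 2)                 # ~ 1/F exactly
  expect_equal(evaporative_delta_T(6, 0.5, 43990, 1.01, 10, 1106),
               2 * dT10)                       # linear in Es
  expect_equal(evaporative_delta_T(3, 1.0, 43990, 1.01, 10, 1106),
               2 * dT10)                       # linear in A
  expect_equal(evaporative_delta_T(0, 0.5, 43990, 1.01, 10, 1106), 0)
  expect_error(evaporative_delta_T(3, 0.5, 43990, 0, 10, 1106),
               class = "cf_invalid_parameter")
})

test_that("moist_air_cp lies between dry-air and vapor heat capacities", {
  cp <- moist_air_cp(psychrometric_state(298.15, 96000, 0.8))
  expect_gt(cp, 1005)
  expect_lt(cp, 1100)  # standard psychrometrics, NOT the published 1106
  expect_equal(moist_air_cp(psychrometric_state(298.15, 96000, 0)), 1005)
})

test_that("generator round trip recovers configured transpiration within 2%", {
  spec <- experiment_spec(n_plant = 1, n_background = 1, n_soil = 1,
                          duration_days = 0.5, record_interval_s = 30)
  exp <- generate_experiment(spec)
  pc <- pipeline_config(exp$configs, exp$schedule,
                        pressure_Pa = spec$pressure_Pa,
                        temperature_K = spec$temperature_K)
  res <- run_pipeline(pc, exp$log, exp$inlet)
  gx <- res$gas_exchange
  tt <- exp$truth_funs$transpiration(gx$time_s)
  sel <- tt > 0.5 * spec$transpiration_peak_mmol
  expect_lt(max(abs(gx$transpiration_mmol_m2_s[sel] - tt[sel]) / tt[sel]), 0.02)
  at <- exp$truth_funs$assimilation(gx$time_s)
  sel <- at > 0.5 * spec$assimilation_peak_umol
  expect_lt(max(abs(gx$assimilation_umol_m2_s[sel] - at[sel]) / at[sel]), 0.02)
})
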