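# Forward chamber model and its inversion.

test_that("time_constant follows V/F and rejects bad input", {
  expect_equal(time_constant(40, 10), 4)
  expect_equal(5 * time_constant(40, 10), 20)
  expect_equal(5 * time_constant(40, 15), 40 / 3, tolerance = 1e-12)
  expect_equal(time_constant(1, 1), 1)
  expect_error(time_constant(0, 10), class = "cf_invalid_parameter")
  expect_error(time_constant(40, -1), class = "cf_invalid_parameter")
})

test_that("exchange_fraction matches the well-mixed model", {
  expect_equal(exchange_fraction(0, 123), 0)
  expect_equal(exchange_fraction(5 * 240, 240), 1 - exp(-5), tolerance = 1e-12)
  expect_gt(exchange_fraction(5 * 240, 240), 0.99)
  expect_equal(exchange_fraction(240, 240), 1 - exp(-1), tolerance = 1e-12)
  expect_error(exchange_fraction(-1, 240), class = "cf_invalid_parameter")
})

test_that("simulate_concentration reproduces the closed-form solutions", {
  cfg <- fix_cfg()                       # tau = 4 min = 240 s
  grid <- seq(0, 1200, by = 1)

  # equilibrium: E = 0, c_in = c(0) = k
  s <- simulate_concentration(cfg, NULL, inlet = 7, time_grid = grid,
                              initial_concentration = 7)
  expect_equal(s$value, rep(7, length(grid)), tolerance = 1e-9)

  # pure decay: c(t) = c0 exp(-t/tau), value at tau is c0/e
  s <- simulate_concentration(cfg, NULL, inlet = 0, time_grid = grid,
                              initial_concentration = 100)
  expect_equal(s$value, 100 * exp(-grid / 240), tolerance = 1e-7)
  expect_equal(s$value[grid == 240], 100 / exp(1), tolerance = 1e-7)

  # plateau E*A/F within 1% after 5 tau
  em <- emission_profile("voc", "constant", rate = 2)
  s <- simulate_concentration(cfg, em, inlet = 0,
                              time_grid = seq(0, 5 * 240, by = 5))
  plateau <- 2 * 0.1 / (10 / 6e4)
  expect_equal(tail(s$value, 1), plateau * (1 - exp(-5)), tolerance = 1e-6)
  expect_lt(abs(tail(s$value, 1) - plateau) / plateau, 0.01)
})

test_that("simulate_concentration validates its inputs", {
  cfg <- fix_cfg()
  expect_error(simulate_concentration(cfg, NULL, 0, c(0, 0, 1)),
               class = "cf_input_error")
  short_inlet <- fix_series(c(0, 10), c(1, 1))
  expect_error(simulate_concentration(cfg, NULL, short_inlet, seq(0, 100, 10)),
               class = "cf_input_error")
})

test_that("steady_state_emission implements (F/A) * delta-c in SI", {
  expect_equal(steady_state_emission(10, 0.1, 5, 5), 0)
  # 6 L/min = 1e-4 m3/s; (1e-4 / 0.1) * 1 = 1e-3
  expect_equal(steady_state_emission(6, 0.1, 1, 0), 1e-3, tolerance = 1e-12)
  expect_lt(steady_state_emission(6, 0.1, 0, 1), 0)  # net uptake
  expect_error(steady_state_emission(6, 0, 1, 0),
               class = "cf_invalid_parameter")
})

test_that("steady-state inversion recovers the configured emission (< 0.1%)", {
  cfg <- fix_cfg()
  E_true <- 3.7
  em <- emission_profile("voc", "constant", rate = E_true)
  s <- simulate_concentration(cfg, em, inlet = 0,
                              time_grid = seq(0, 12 * 240, by = 10))
  E_hat <- steady_state_emission(cfg$inlet_flow_lpm, cfg$leaf_area_m2,
                                 tail(s$value, 1))
  expect_lt(abs(E_hat - E_true) / E_true, 1e-3)
})

test_that("dynamic_emission equals steady_state_emission on constant series", {
  cfg <- fix_cfg()
  ser <- fix_series(seq(0, 100, 10), rep(50, 11))
  dyn <- dynamic_emission(ser, 2, cfg)
  expect_equal(dyn$value,
               rep(steady_state_emission(10, 0.1, 50, 2), 11),
               tolerance = 1e-12)
  expect_error(dynamic_emission(fix_series(c(0, 1), c(1, 2)), 0, cfg),
               class = "cf_insufficient_data")
})

test_that("dynamic_emission recovers a step within 2% away from edges", {
  cfg <- fix_cfg()
  em <- emission_profile("voc", "step", rate0 = 1, rate1 = 4, t_step = 1200)
  grid <- seq(0, 3600, by = 5)
  s <- simulate_concentration(cfg, em, inlet = 0, time_grid = grid)
  dyn <- dynamic_emission(s, 0, cfg)
  # well after the step (> 2 tau past it), away from grid boundaries
  late <- grid > 1200 + 2 * 240 & grid < 3500
  expect_lt(max(abs(dyn$value[late] - 4) / 4), 0.02)
  early <- grid > 100 & grid < 1100
  expect_lt(max(abs(dyn$value[early] - 1) / 1), 0.02)
})

test_that("dynamic o simulate is identity on a smooth diurnal sine", {
  cfg <- fix_cfg()  # tau = 240 s -> dt = tau/20 = 12 s
  em <- emission_profile("voc", "diurnal_sine", peak = 5)
  grid <- seq(0, 43200, by = 12)
  s <- simulate_concentration(cfg, em, inlet = 0, time_grid = grid)
  dyn <- dynamic_emission(s, 0, cfg)
  truth <- em$evaluate(grid)
  mid <- truth > 0.1 * 5 & grid > 600 & grid < 42600
  expect_lt(max(abs(dyn$value[mid] - truth[mid]) / truth[mid]), 0.02)
})

test_that("relaxation toward c_in is monotone and never overshoots", {
  cfg <- fix_cfg()
  for (case in list(c(c0 = 100, cin = 10), c(c0 = 0, cin = 25))) {
    s <- simulate_concentration(cfg, NULL, inlet = case[["cin"]],
                                time_grid = seq(0, 2400, 10),
                                initial_concentration = case[["c0"]])
    d <- diff(s$value)
    if (case[["c0"]] > case[["cin"]]) expect_true(all(d <= 1e-9))
    else expect_true(all(d >= -1e-9))
    span <- range(c(case[["c0"]], case[["cin"]]))
    expect_true(all(s$value >= span[1] - 1e-6 & s$value <= span[2] + 1e-6))
  }
})

test_that("simulation is linear in the emission profile", {
  cfg <- fix_cfg()
  grid <- seq(0, 3600, 30)
  e1 <- emission_profile("a", "constant", rate = 2)
  e2 <- emission_profile("b", "diurnal_sine", peak = 4)
  alpha <- 0.7; beta <- -1.3
  comb <- emission_profile("ab", "custom",
                           fun = function(t) alpha * e1$evaluate(t) + beta * e2$evaluate(t),
                           emission_only = FALSE)
  s1 <- simulate_concentration(cfg, e1, 0, grid)$value
  s2 <- simulate_concentration(cfg, e2, 0, grid)$value
  sc <- simulate_concentration(cfg, comb, 0, grid)$value
  scale <- max(abs(sc))
  expect_lt(max(abs(sc - (alpha * s1 + beta * s2))) / scale, 1e-6)
})

test_that("chamber acts as a first-order low-pass filter", {
  cfg <- fix_cfg()  # tau = 240 s
  tau <- 240
  for (om_tau in c(0.5, 1, 3)) {
    omega <- om_tau / tau
    em <- emission_profile("voc", "custom", fun = function(t) sin(omega * t),
                           emission_only = FALSE)
    period <- 2 * pi / omega
    grid <- seq(0, 10 * period, by = min(tau, period) / 40)
    s <- simulate_concentration(cfg, em, 0, grid)
    # amplitude from a sin/cos regression over the settled tail
    tail_i <- grid > 7 * period
    X <- cbind(sin(omega * grid[tail_i]), cos(omega * grid[tail_i]))
    amp <- sqrt(sum(coef(lm(s$value[tail_i] ~ X - 1))^2))
    quasi_static <- 1 * cfg$leaf_area_m2 / (cfg$inlet_flow_lpm / 6e4)
    expect_equal(amp / quasi_static, 1 / sqrt(1 + om_tau^2), tolerance = 0.03)
  }
})
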