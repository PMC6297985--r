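# Demultiplexing, lag discard, background correction, inlet alignment.

test_that("single cuvette with zero lag is the identity", {
  sched <- valve_schedule("a", dwell_s = 100, lag_s = 0)
  log <- data.frame(time_s = 0:99, active_cuvette = "a",
                    channel = "voc", value = sin(0:99))
  d <- demultiplex(log, sched)
  expect_equal(d$discarded, 0)
  expect_equal(d$series$a$voc$time_s, as.numeric(0:99))
  expect_equal(d$series$a$voc$value, sin(0:99))
})

test_that("lag discard keeps dwell - lag records per window", {
  ids <- c("a", "b", "c")
  sched <- valve_schedule(ids, dwell_s = 300, lag_s = 60)
  log <- fix_log(ids, dwell = 300, n_cycles = 2, by = 1)
  d <- demultiplex(log, sched)
  expect_equal(d$kept + d$discarded, nrow(log))     # record conservation
  expect_equal(d$discarded, 60 * 3 * 2)             # 60 per window
  for (id in ids)
    expect_equal(length(d$series[[id]]$voc$time_s), 240 * 2)
  # order preserved within each cuvette
  for (id in ids)
    expect_false(is.unsorted(d$series[[id]]$voc$time_s, strictly = TRUE))
})

test_that("24 cuvettes x 300 s dwell revisit every 7200 s", {
  ids <- sprintf("c%02d", 1:24)
  sched <- valve_schedule(ids, dwell_s = 300, lag_s = 30)
  log <- fix_log(ids, dwell = 300, n_cycles = 2, by = 60)
  d <- demultiplex(log, sched)
  t1 <- d$series$c01$voc$time_s
  # first kept sample of consecutive visits is one full cycle (~2 h) apart
  expect_equal(t1[length(t1) / 2 + 1] - t1[1], 24 * 300)
})

test_that("record conservation holds per channel", {
  ids <- c("a", "b")
  sched <- valve_schedule(ids, dwell_s = 60, lag_s = 10)
  log <- fix_log(ids, dwell = 60, n_cycles = 3, by = 2,
                 channels = c("voc", "co2_ppm"))
  d <- demultiplex(log, sched)
  for (ch in c("voc", "co2_ppm")) {
    row <- d$counts[d$counts$channel == ch, ]
    expect_equal(row$kept + row$discarded, sum(log$channel == ch))
  }
})

test_that("unknown cuvette ids and bad logs are rejected", {
  sched <- valve_schedule(c("a", "b"), dwell_s = 60, lag_s = 5)
  log <- data.frame(time_s = 0:9, active_cuvette = "zz",
                    channel = "voc", value = 1)
  expect_error(demultiplex(log, sched), class = "cf_validation_error")
  expect_error(demultiplex(data.frame(time_s = 1, value = 2), sched),
               class = "cf_validation_error")
})

test_that("demultiplex reconstructs nominal timing without annotations", {
  ids <- c("a", "b")
  sched <- valve_schedule(ids, dwell_s = 100, lag_s = 20, start_time_s = 0)
  log <- data.frame(time_s = 0:399, channel = "voc", value = 0:399)
  d <- demultiplex(log, sched)
  expect_equal(range(d$series$a$voc$time_s %% 200), c(20, 99))
  expect_equal(d$kept, 2 * 2 * 80)
})

test_that("background self-subtraction yields zero", {
  t <- seq(0, 1000, 50)
  ser <- fix_series(t, 3 + 0.01 * t)
  corr <- background_correct(ser, list(ser))
  expect_equal(corr$value, rep(0, length(t)), tolerance = 1e-12)
})

test_that("background correction is exact on linear and cubic backgrounds", {
  poly3 <- function(t) 5 + 0.02 * t - 3e-6 * t^2 + 2e-9 * t^3
  line <- function(t) 2 + 0.005 * t
  t_bg <- seq(0, 2000, 125)         # background sampled on its own grid
  t_target <- seq(62.5, 1937.5, 125) # alternating/offset times
  for (f in list(line, poly3)) {
    bg <- fix_series(t_bg, f(t_bg), id = "bg")
    signal <- 100 * sin(t_target / 300)
    target <- fix_series(t_target, signal + f(t_target))
    corr <- background_correct(target, list(bg))
    expect_equal(corr$value, signal, tolerance = 1e-9)
  }
})

test_that("constant background offset is removed to machine precision", {
  cfg <- fix_cfg()
  em <- emission_profile("voc", "constant", rate = 2)
  grid <- seq(0, 2400, 20)
  clean <- simulate_concentration(cfg, em, 0, grid)
  b <- 55.5
  contaminated <- fix_series(grid, clean$value + b)
  bg <- fix_series(seq(0, 2400, 100), rep(b, 25), id = "bg")
  corr <- background_correct(contaminated, list(bg))
  expect_equal(corr$value, clean$value, tolerance = 1e-10)
})

test_that("multiple backgrounds sharing timestamps are averaged", {
  t <- seq(0, 1000, 100)
  bg1 <- fix_series(t, rep(10, length(t)), id = "b1")
  bg2 <- fix_series(t, rep(20, length(t)), id = "b2")
  target <- fix_series(t, rep(100, length(t)))
  corr <- background_correct(target, list(bg1, bg2))
  expect_equal(corr$value, rep(85, length(t)), tolerance = 1e-10)
})

test_that("background errors and flags behave as contracted", {
  t <- seq(0, 1000, 100)
  target <- fix_series(t, rep(1, length(t)))
  expect_error(background_correct(target, list()),
               class = "cf_configuration_error")
  # coverage gap > 2 cycles -> warning, endpoint value held
  bg <- fix_series(c(0, 50, 5000, 5050), c(1, 1, 1, 1), id = "bg")
  expect_warning(background_correct(fix_series(c(0, 6000), c(2, 2)),
                                    list(bg), cycle_s = 600),
                 "coverage gap")
  # negative corrected values retained and counted
  corr <- background_correct(fix_series(t, rep(0, length(t))),
                             list(fix_series(t, rep(1, length(t)), id = "bg")))
  expect_equal(corr$value, rep(-1, length(t)))
  expect_equal(attr(corr, "n_negative"), length(t))
  # idempotence: correcting with a zero background changes nothing
  zero_bg <- fix_series(t, rep(0, length(t)), id = "z")
  corr2 <- background_correct(corr, list(zero_bg))
  expect_equal(corr2$value, corr$value)
})

test_that("align_pair interpolates, clips and flags", {
  outlet <- fix_series(c(25, 50, 150), c(1, 2, 3))
  inlet <- fix_series(c(0, 100), c(0, 10), id = "inlet")
  p <- align_pair(outlet, inlet)
  expect_equal(p$inlet, c(2.5, 5, 10))
  expect_equal(p$clipped, c(FALSE, FALSE, TRUE))
  const_inlet <- fix_series(c(0, 200), c(4, 4), id = "inlet")
  expect_equal(align_pair(outlet, const_inlet)$inlet, rep(4, 3))
  disjoint <- fix_series(c(1000, 2000), c(1, 2), id = "inlet")
  expect_error(align_pair(outlet, disjoint), class = "cf_alignment_error")
})
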