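test_that("simulated core has the expected sample count and is conservative", {
  cfg <- noise_free_config()
  core <- simulate_core(cfg, seed = 1)
  # 46 years at exactly 9.6 mm/yr sampled every 0.25 mm: 46*9.6/0.25 + 1
  expect_equal(nrow(core$ba_ca), 1767)
  expect_equal(core$truth$total_depth_mm, 46 * 9.6, tolerance = 1e-9)
  # conservation: calendar-year extensions sum to the full skeleton depth
  expect_equal(sum(core$truth$calendar_extension$extension_mm),
               core$truth$total_depth_mm, tolerance = 1e-9)
})

test_that("same (config, seed) reproduces bit-identical cores", {
  cfg <- synth_config()
  a <- simulate_core(cfg, seed = 3)
  b <- simulate_core(cfg, seed = 3)
  expect_identical(a$ba_ca$value, b$ba_ca$value)
  expect_identical(a$sr_ca$value, b$sr_ca$value)
  expect_identical(a$truth$annual_extension, b$truth$annual_extension)
  c <- simulate_core(cfg, seed = 4)
  expect_false(identical(a$ba_ca$value, c$ba_ca$value))
})

test_that("degenerate environment settings collapse to their limits", {
  cfg <- noise_free_config(sst_amplitude = 0,
                           ba_trend_knots = data.frame(year = c(1968, 2014),
                                                       level = c(0, 0)),
                           ba_seasonal_amplitude = 0,
                           spike_events = data.frame(year = integer(),
                                                     month = integer(),
                                                     magnitude = numeric(),
                                                     lag_months = numeric(),
                                                     decay_months = numeric()))
  env <- simulate_environment(cfg, seed = 1)
  expect_true(all(env$sst$value == cfg$sst_mean))
  expect_true(all(env$ba_sw$value == cfg$ba_baseline))
  # constant SST + no proxy noise => flat Sr/Ca profile
  core <- simulate_core(cfg, seed = 1)
  expect_equal(diff(range(core$sr_ca$value)), 0)
})

test_that("flat knots with no spikes leave exactly the seasonal climatology", {
  cfg <- noise_free_config(
    ba_trend_knots = data.frame(year = c(1968, 2014), level = c(0, 0)),
    spike_events = data.frame(year = integer(), month = integer(),
                              magnitude = numeric(), lag_months = numeric(),
                              decay_months = numeric()))
  env <- simulate_environment(cfg, seed = 1)
  clim <- tapply(env$ba_sw$value - cfg$ba_baseline, env$ba_sw$month, mean)
  expect_equal(as.numeric(clim[as.character(1:12)]),
               cfg$ba_seasonal_amplitude * cos(2 * pi * (1:12 - 9) / 12),
               tolerance = 1e-12)
})

test_that("inject_spike is additive, lagged, and exact in its limits", {
  m <- make_months(240, 2000)
  base <- monthly_series(m$year, m$month, rep(1, 240))

  expect_equal(inject_spike(base, 2005, 6, 0, 3, 2)$value, base$value)

  imp <- inject_spike(base, 2005, 6, 1.5, 0, 0)
  hit <- which(imp$year == 2005 & imp$month == 6)
  expect_equal(imp$value[hit], 1 + 1.5)
  expect_equal(imp$value[-hit], base$value[-hit])

  # closed-form maximum: June yr 2005, lag 3 -> onset (= maximum) September
  sp <- inject_spike(base, 2005, 6, 1.5, 3, 2)
  peak <- which.max(sp$value)
  expect_equal(c(sp$year[peak], sp$month[peak]), c(2005, 9))

  # superposition: two overlapping spikes equal the sum of single injections
  s1 <- inject_spike(base, 2005, 6, 1.0, 2, 3)
  s2 <- inject_spike(base, 2005, 8, 0.7, 1, 2)
  s12 <- inject_spike(s1, 2005, 8, 0.7, 1, 2)
  expect_equal(s12$value, s1$value + s2$value - base$value, tolerance = 1e-12)

  expect_error(inject_spike(base, 2005, 6, -1, 0, 2),
               class = "coralba_config_error")
  expect_error(inject_spike(base, 2030, 1, 1, 0, 2),
               class = "coralba_config_error")
})

test_that("sampled profiles carry the configured analytical noise", {
  # constant environment isolates the multiplicative noise: the sample RSD
  # of each profile should sit within 20% of the configured RSD
  cfg <- synth_config(sst_amplitude = 0, sst_noise = 0, extension_sdlog = 0,
                      ba_trend_knots = data.frame(year = c(1968, 2014),
                                                  level = c(0, 0)),
                      ba_seasonal_amplitude = 0, density_amplitude = 0,
                      spike_events = data.frame(year = integer(),
                                                month = integer(),
                                                magnitude = numeric(),
                                                lag_months = numeric(),
                                                decay_months = numeric()))
  core <- simulate_core(cfg, seed = 11)
  for (nm in c("sr_ca", "mg_ca", "ba_ca")) {
    rsd_hat <- sd(core[[nm]]$value) / mean(core[[nm]]$value)
    rsd_cfg <- attr(core[[nm]], "rsd")
    expect_lt(abs(rsd_hat - rsd_cfg) / rsd_cfg, 0.2)
  }
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(rsd_ba = 0.5), class = "coralba_config_error")
  expect_error(synth_config(mean_extension_mm_yr = -1),
               class = "coralba_config_error")
  expect_error(synth_config(ba_trend_knots = data.frame(year = c(1990, 1980),
                                                        level = c(0, 1))),
               class = "coralba_config_error")
  expect_error(simulate_core(synth_config(sampling_interval_mm = 20), seed = 1),
               class = "coralba_resolution_error")
  expect_error(
    simulate_environment(synth_config(
      ba_trend_knots = data.frame(year = c(1900, 2014), level = c(0, 0))),
      seed = 1),
    class = "coralba_config_error")
})
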