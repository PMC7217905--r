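test_that("extrema of a pure cosine profile fall at the analytic maxima", {
  d <- seq(0, 96, by = 0.25)
  ds <- depth_series(d, cos(2 * pi * d / 9.6), proxy = "sr_ca")
  mx <- detect_extrema(ds, "maxima", min_separation_mm = 4)
  expect_equal(mx$depth_mm, seq(9.6, 86.4, by = 9.6), tolerance = 0.05)
  mn <- detect_extrema(ds, "minima", min_separation_mm = 4)
  expect_equal(mn$depth_mm, seq(4.8, 91.2, by = 9.6), tolerance = 0.05)
})

test_that("a monotone ramp has no extrema", {
  ds <- depth_series(seq(0, 50, 0.25), seq(0, 50, 0.25), proxy = "sr_ca")
  expect_error(detect_extrema(ds, "maxima"),
               class = "coralba_chronology_error")
})

test_that("noise-free chronology recovers truth exactly", {
  core <- simulate_core(noise_free_config(), seed = 2)
  mx <- detect_extrema(core$sr_ca, "maxima")
  truth_w <- core$truth$tiepoints[core$truth$tiepoints$kind == "winter", ]
  expect_equal(nrow(mx), nrow(truth_w))
  expect_lt(max(abs(sort(mx$depth_mm) - sort(truth_w$depth_mm))), 0.25)

  ch <- run_chronology(core)
  m <- dplyr::inner_join(ch$tiepoints, core$truth$tiepoints,
                         by = c("year", "kind"), suffix = c("", ".t"))
  expect_equal(nrow(m), nrow(core$truth$tiepoints))
  expect_identical(m$month, m$month.t)     # dates exact without noise
})

test_that("tie dates alternate February/August counting back without SST", {
  mx <- tibble::tibble(depth_mm = c(5, 24.2))
  mn <- tibble::tibble(depth_mm = 14.5)
  tp <- build_tiepoints(mx, mn, collection)
  expect_equal(tp$kind, c("winter", "summer", "winter"))
  expect_equal(tp$month, c(2L, 8L, 2L))
  expect_equal(tp$year, c(2014L, 2013L, 2013L))
  expect_true(all(diff(month_index(tp$year, tp$month)) < 0))

  # non-alternating extrema are rejected
  expect_error(build_tiepoints(tibble::tibble(depth_mm = c(5, 10)),
                               tibble::tibble(depth_mm = numeric()),
                               collection),
               class = "coralba_chronology_error")
})

test_that("maxima inside the instrumental span need SST winters", {
  m <- make_months(24, 2013, 1)   # SST covers 2013-2014: two winters only
  sst <- monthly_series(m$year, m$month, 25 + 4 * cos(2 * pi * (m$month - 8) / 12))
  mx <- tibble::tibble(depth_mm = c(5, 14.6, 24.2))
  mn <- tibble::tibble(depth_mm = c(9.8, 19.4))
  expect_error(
    build_tiepoints(mx, mn, c(2014, 10), sst = sst,
                    instrumental_start = c(2011, 1)),
    class = "coralba_chronology_error")
})

test_that("the age model interpolates, extrapolates and caps correctly", {
  tp <- tibble::tibble(depth_mm = c(0, 9.6),
                       time = c(month_time(2014, 8), month_time(2013, 8)))
  model <- build_age_model(tp, collection)
  # linear midpoint: 4.8 mm -> February 2014
  expect_equal(predict_time(model, 4.8), month_time(2014, 2))
  # tie points map to their own dates exactly
  expect_equal(predict_time(model, tp$depth_mm), tp$time)
  # below the last tie: extrapolate the last rate
  expect_equal(predict_time(model, 19.2), month_time(2012, 8))
  # inverse identity on the covered range
  tt <- seq(month_time(2013, 8), month_time(2014, 8), length.out = 11)
  expect_equal(predict_time(model, predict_depth(model, tt)), tt,
               tolerance = 1e-10)

  expect_error(build_age_model(tp[1, ], collection),
               class = "coralba_chronology_error")
  bad <- tibble::tibble(depth_mm = c(0, 9.6),
                        time = c(month_time(2013, 8), month_time(2014, 8)))
  expect_error(build_age_model(bad, collection),
               class = "coralba_chronology_error")
})

test_that("monthly resampling composes linear maps and never overshoots", {
  tp <- tibble::tibble(depth_mm = c(0, 96),
                       time = c(month_time(2014, 8), month_time(2004, 8)))
  model <- build_age_model(tp, c(2014, 10))
  d <- seq(0, 96, by = 0.25)
  lin <- depth_series(d, 2 + 0.1 * d, proxy = "ba_ca")
  ms <- resample_monthly(lin, model)
  # linear in depth + uniform growth => linear in time
  expect_lt(max(abs(diff(diff(ms$value)))), 1e-9)

  cst <- depth_series(d, rep(3.8, length(d)), proxy = "ba_ca")
  expect_true(all(resample_monthly(cst, model)$value == 3.8))

  set.seed(9)
  rnd <- depth_series(d, rnorm(length(d)), proxy = "ba_ca")
  rs <- resample_monthly(rnd, model)
  expect_gte(min(rs$value), min(rnd$value))
  expect_lte(max(rs$value), max(rnd$value))
})

test_that("noise-free resampled Ba/Ca matches the truth forcing closely", {
  # spike-free configuration: the bound concerns the smooth seasonal/trend
  # component; exponential spike onsets are kinks that linear depth
  # resampling necessarily rounds
  cfg <- noise_free_config(spike_events = data.frame(
    year = integer(), month = integer(), magnitude = numeric(),
    lag_months = numeric(), decay_months = numeric()))
  core <- simulate_core(cfg, seed = 5)
  ch <- run_chronology(core)
  m <- dplyr::inner_join(ch$ba_monthly, core$truth$ba_sw,
                         by = c("year", "month"), suffix = c("", ".t"))
  expect_gt(nrow(m), 500)
  expect_lt(max(abs(m$value - m$value.t)),
            0.02 * 2 * cfg$ba_seasonal_amplitude)
})

test_that("with default noise, tie dates land within a month of truth", {
  hits <- ext_ok <- numeric(0)
  for (s in 1:20) {
    core <- simulate_core(synth_config(), seed = s)
    ch <- run_chronology(core)
    m <- dplyr::inner_join(ch$tiepoints, core$truth$tiepoints,
                           by = c("year", "kind"), suffix = c("", ".t"))
    dm <- month_index(m$year, m$month) - month_index(m$year, m$month.t)
    hits <- c(hits, abs(dm) <= 1)
    me <- dplyr::inner_join(annual_extension(ch$tiepoints),
                            core$truth$annual_extension,
                            by = "year", suffix = c("", ".t"))
    ext_ok <- c(ext_ok, abs(me$extension_mm - me$extension_mm.t) <= 0.25)
  }
  expect_gte(mean(hits), 0.95)
  expect_gte(mean(ext_ok), 0.95)
})

test_that("proxy calibration is exact on exact data and refuses short overlap", {
  m <- make_months(120, 1990)
  sst <- monthly_series(m$year, m$month,
                        25 + 4 * cos(2 * pi * (m$month - 8) / 12) +
                          0.3 * sin(seq_len(120) / 5))
  proxy <- monthly_series(m$year, m$month, 10 - 0.06 * sst$value)
  cal <- suppressWarnings(calibrate_sst_proxy(proxy, sst))
  expect_equal(cal$slope, -0.06, tolerance = 1e-10)
  expect_equal(cal$intercept, 10, tolerance = 1e-8)
  expect_equal(cal$r, -1, tolerance = 1e-10)

  # inverse identity: reconstructing from fitted values returns SST
  rec <- reconstruct_sst(proxy, cal)
  expect_equal(rec$value, sst$value, tolerance = 1e-8)

  short <- monthly_series(m$year[1:12], m$month[1:12], proxy$value[1:12])
  expect_error(calibrate_sst_proxy(short, sst),
               class = "coralba_calibration_error")

  # independent proxy: negligible correlation at n = 120
  set.seed(31)
  indep <- monthly_series(m$year, m$month, rnorm(120))
  expect_lt(abs(calibrate_sst_proxy(indep, sst)$r), 0.3)
})

test_that("delta Sr/Ca isolates departures from the thermometer", {
  m <- make_months(60, 2000)
  sst <- monthly_series(m$year, m$month,
                        25 + 4 * cos(2 * pi * (m$month - 8) / 12) +
                          0.2 * cos(seq_len(60) / 3))
  proxy <- monthly_series(m$year, m$month, 10 - 0.06 * sst$value)
  cal <- suppressWarnings(calibrate_sst_proxy(proxy, sst))
  d0 <- delta_srca(proxy, cal, sst)
  expect_lt(max(abs(d0$value)), 1e-8)

  bump <- proxy
  hit <- c(10, 25, 40)
  bump$value[hit] <- bump$value[hit] + 0.1
  cal2 <- suppressWarnings(calibrate_sst_proxy(bump, sst))
  d1 <- delta_srca(bump, cal2, sst)
  expect_equal(sort(order(abs(d1$value), decreasing = TRUE)[1:3]), hit)
  expect_equal(unname(d1$value[hit] - mean(d1$value[-hit])), rep(0.1, 3),
               tolerance = 0.02)
})
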