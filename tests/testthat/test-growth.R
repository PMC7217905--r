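test_that("extension rates are the distances between winter tie points", {
  tp <- tibble::tibble(depth_mm = c(0, 9.6, 19.2),
                       year = c(2014L, 2013L, 2012L),
                       month = 2L, kind = "winter",
                       time = month_time(c(2014, 2013, 2012), 2))
  ext <- annual_extension(tp)
  expect_equal(ext$extension_mm, c(9.6, 9.6))
  expect_equal(ext$year, c(2012L, 2013L))
  expect_error(annual_extension(tp[1, ]), class = "coralba_chronology_error")
})

test_that("extensions recover truth and conserve total depth", {
  core <- simulate_core(noise_free_config(), seed = 6)
  ch <- run_chronology(core)
  ext <- annual_extension(ch$tiepoints)
  m <- dplyr::inner_join(ext, core$truth$annual_extension,
                         by = "year", suffix = c("", ".t"))
  expect_equal(nrow(m), nrow(core$truth$annual_extension))
  expect_lt(max(abs(m$extension_mm - m$extension_mm.t)), 0.25)

  # conservation: extensions sum to the span between first and last winter
  w <- ch$tiepoints[ch$tiepoints$kind == "winter", ]
  expect_equal(sum(ext$extension_mm),
               max(w$depth_mm) - min(w$depth_mm), tolerance = 1e-9)

  # sample mean extension near the configured rate on a noisy core
  noisy <- simulate_core(synth_config(), seed = 6)
  ext2 <- annual_extension(run_chronology(noisy)$tiepoints)
  expect_lt(abs(mean(ext2$extension_mm) - 9.6) / 9.6, 0.05)
})

test_that("annual density averages the profile year by year", {
  tp <- tibble::tibble(depth_mm = c(0, 96),
                       time = c(month_time(2014, 8), month_time(2004, 8)))
  model <- build_age_model(tp, c(2014, 10))
  d <- seq(0, 96, by = 0.25)

  cst <- depth_series(d, rep(1.3, length(d)), proxy = "density")
  ad <- annual_density(cst, model)
  expect_true(all(ad$density == 1.3))
  expect_true(all(ad$year %in% 2005:2013))     # complete years only

  # sinusoidal density + uniform growth: annual means near the profile mean
  sine <- depth_series(d, 1.3 + 0.2 * sin(2 * pi * d / 9.6), proxy = "density")
  ad2 <- annual_density(sine, model)
  expect_lt(max(abs(ad2$density - 1.3)) / 1.3, 0.01)

  # a short profile yields fewer years, never fabricated ones
  shorty <- depth_series(d[d <= 48], rep(1.3, sum(d <= 48)), proxy = "density")
  ad3 <- annual_density(shorty, model)
  expect_lt(max(ad3$year), 2014)
  expect_gte(min(ad3$year), 2009)
})

test_that("calcification is extension times density with unit conversion", {
  ext <- tibble::tibble(year = 2000:2002, extension_mm = c(10, 9.6, 8))
  den <- tibble::tibble(year = 2000:2002, density = c(1.2, 1.25, 1.3))
  cr <- calcification_rate(ext, den)
  expect_equal(cr$calcification, c(1.2, 1.2, 1.04))
  # identity: calcification / density * 10 = extension, exactly
  expect_equal(cr$calcification / cr$density * 10, cr$extension_mm,
               tolerance = 1e-12)

  expect_warning(calcification_rate(ext, den[-2, ]), "dropped")
  bad <- tibble::tibble(year = 2000, extension_mm = 0)
  expect_error(calcification_rate(bad, den), class = "coralba_domain_error")
})

test_that("an exact linear response yields r = -1 and the true slope", {
  lp <- tibble::tibble(year = 1968:2013,
                       value = 3.8 + 0.3 * sin(seq_len(46) / 4))
  growth <- tibble::tibble(year = lp$year,
                           extension_mm = 20 - 2 * lp$value,
                           calcification = 2.6 - 0.3 * lp$value)
  gc <- suppressWarnings(growth_vs_lowpass(growth, lp, boundary_year = 1996))
  expect_equal(nrow(gc), 4)
  expect_true(all(abs(gc$r + 1) < 1e-10))
  expect_equal(gc$slope[gc$variable == "calcification"], c(-0.3, -0.3),
               tolerance = 1e-10)
  expect_equal(gc$slope[gc$variable == "extension"], c(-2, -2),
               tolerance = 1e-10)
  expect_equal(gc$n[gc$period == "A"], c(28, 28))
})

test_that("a linear response with noise is recovered within 2 SE", {
  core <- simulate_core(synth_config(), seed = 9)
  ch <- run_chronology(core)
  dec <- decompose_monthly(ch$ba_monthly, exclude_months = 5)
  lp <- suppressMessages(annual_means(dec$lowpass))
  hit <- slopes <- numeric(0)
  for (s in 1:20) {
    set.seed(700 + s)
    noise_sd <- 0.3 * sd(lp$value) / 2        # SNR 2 on the response
    growth <- tibble::tibble(
      year = lp$year,
      extension_mm = 9.6 + rnorm(nrow(lp), 0, 0.3),
      calcification = 2.6 - 0.3 * lp$value + rnorm(nrow(lp), 0, noise_sd))
    gc <- growth_vs_lowpass(growth, lp)
    cc <- gc[gc$variable == "calcification", ]
    hit <- c(hit, abs(cc$slope - (-0.3)) <= 2 * cc$slope_se)
    slopes <- c(slopes, cc$slope)
  }
  expect_gte(mean(hit), 0.8)                  # ~0.94 expected per fit
  expect_lt(abs(mean(slopes) + 0.3), 0.05)
})

test_that("independent growth shows no spurious correlation", {
  core <- simulate_core(synth_config(), seed = 10)
  ch <- run_chronology(core)
  dec <- decompose_monthly(ch$ba_monthly, exclude_months = 5)
  lp <- suppressMessages(annual_means(dec$lowpass))
  big_r <- vapply(1:20, function(s) {
    set.seed(800 + s)
    growth <- tibble::tibble(year = lp$year,
                             extension_mm = 9.6 + rnorm(nrow(lp), 0, 0.5),
                             calcification = 1.2 + rnorm(nrow(lp), 0, 0.1))
    gc <- growth_vs_lowpass(growth, lp)
    max(abs(gc$r))
  }, numeric(1))
  expect_gte(mean(big_r < 0.5), 0.9)
})
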