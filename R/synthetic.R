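# Forward simulator: a virtual massive-coral core with known truth. The
# generator emulates the statistical structure of a ~46-year subtropical
# bay record: seasonal SST anticorrelated with Sr/Ca, a seawater Ba/Ca
# forcing made of a piecewise multidecadal trend plus a seasonal cycle plus
# lagged exponential spike events, uniform-by-default intra-annual growth,
# and multiplicative analytical noise at instrument RSDs.

with_seed_ <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic coral core
#'
#' Defaults encode the study conditions: 46 years of growth ending at an
#' October collection, mean extension 9.6 mm/yr sampled every 0.25 mm,
#' warmest SST in August and coolest in February, Sr/Ca declining ~0.06
#' mmol/mol per degree C, a Ba/Ca forcing whose multidecadal component rises
#' to 1980, falls to 1995 and rises again to collection (trend shift at
#' 1995/96), a seasonal term peaking in September, four flood spikes with
#' lags of 3, 0, 2 and 4 months, and analytical RSDs of 2.24% (Ba/Ca),
#' 0.17% (Sr/Ca), 0.73% (Mg/Ca).
#'
#' @param n_years Years of growth ending at the collection month.
#' @param collection_year,collection_month Collection date (youngest skeleton).
#' @param mean_extension_mm_yr Mean annual extension rate (mm/yr).
#' @param extension_sdlog Lognormal sdlog of per-year extension variability.
#' @param sampling_interval_mm Microsampling interval (mm).
#' @param growth_profile `"uniform"` (constant monthly growth) or
#'   `"winter_slowdown"` (growth reduced in the coolest months).
#' @param sst_mean,sst_amplitude,sst_noise SST seasonal cycle (deg C): mean,
#'   cosine amplitude (warmest August, coolest February), monthly noise sd.
#' @param srca_intercept,srca_slope Sr/Ca thermometer (mmol/mol; slope < 0).
#' @param mgca_intercept,mgca_slope Mg/Ca thermometer (mmol/mol; slope > 0).
#' @param ba_baseline Seawater-equilibrium Ba/Ca baseline (umol/mol).
#' @param ba_trend_knots Tibble/data frame with `year`, `level` columns:
#'   piecewise-linear multidecadal anomaly added to the baseline.
#' @param ba_seasonal_amplitude,ba_seasonal_peak_month Seasonal modulation of
#'   the Ba forcing (umol/mol; peak month 9 = September spike season).
#' @param spike_events Tibble/data frame with `year`, `month`, `magnitude`
#'   (umol/mol), `lag_months`, `decay_months` columns: documented-event
#'   analogue spikes injected into the forcing.
#' @param density_mean,density_amplitude Skeletal density seasonal cycle
#'   (g/cm^3).
#' @param rsd_ba,rsd_sr,rsd_mg,rsd_density Fractional analytical RSDs.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_years = 46,
                         collection_year = 2014,
                         collection_month = 10,
                         mean_extension_mm_yr = 9.6,
                         extension_sdlog = 0.08,
                         sampling_interval_mm = 0.25,
                         growth_profile = c("uniform", "winter_slowdown"),
                         sst_mean = 25, sst_amplitude = 4, sst_noise = 0.3,
                         srca_intercept = 10.5, srca_slope = -0.06,
                         mgca_intercept = 3.2, mgca_slope = 0.04,
                         ba_baseline = 3.8,
                         ba_trend_knots = NULL,
                         ba_seasonal_amplitude = 0.15,
                         ba_seasonal_peak_month = 9,
                         spike_events = NULL,
                         density_mean = 1.3, density_amplitude = 0.1,
                         rsd_ba = 0.0224, rsd_sr = 0.0017, rsd_mg = 0.0073,
                         rsd_density = 0.01) {
  growth_profile <- match.arg(growth_profile)
  if (is.null(ba_trend_knots)) {
    ba_trend_knots <- tibble(
      year = c(1968, 1980, 1995, 2014),
      level = c(0.00, 0.25, -0.05, 0.35)
    )
  }
  ba_trend_knots <- as_tibble(ba_trend_knots)
  if (is.unsorted(ba_trend_knots$year, strictly = TRUE)) {
    abort("trend knots must have strictly increasing years",
          class = "coralba_config_error")
  }
  if (is.null(spike_events)) {
    spike_events <- tibble(
      year = c(1977, 1990, 1991, 2010),
      month = c(6, 9, 8, 10),
      magnitude = c(0.8, 0.9, 0.85, 1.5),
      lag_months = c(3, 0, 2, 4),
      decay_months = c(2, 2, 2, 2)
    )
  }
  spike_events <- as_tibble(spike_events)
  cfg <- list(
    n_years = n_years, collection_year = collection_year,
    collection_month = collection_month,
    mean_extension_mm_yr = mean_extension_mm_yr,
    extension_sdlog = extension_sdlog,
    sampling_interval_mm = sampling_interval_mm,
    growth_profile = growth_profile,
    sst_mean = sst_mean, sst_amplitude = sst_amplitude, sst_noise = sst_noise,
    srca_intercept = srca_intercept, srca_slope = srca_slope,
    mgca_intercept = mgca_intercept, mgca_slope = mgca_slope,
    ba_baseline = ba_baseline, ba_trend_knots = ba_trend_knots,
    ba_seasonal_amplitude = ba_seasonal_amplitude,
    ba_seasonal_peak_month = ba_seasonal_peak_month,
    spike_events = spike_events,
    density_mean = density_mean, density_amplitude = density_amplitude,
    rsd_ba = rsd_ba, rsd_sr = rsd_sr, rsd_mg = rsd_mg,
    rsd_density = rsd_density
  )
  positives <- c("n_years", "mean_extension_mm_yr", "sampling_interval_mm",
                 "ba_baseline", "density_mean")
  for (p in positives) {
    if (cfg[[p]] <= 0) {
      abort(sprintf("config field '%s' must be positive", p),
            class = "coralba_config_error")
    }
  }
  for (p in c("rsd_ba", "rsd_sr", "rsd_mg", "rsd_density")) {
    if (cfg[[p]] < 0 || cfg[[p]] >= 0.1) {
      abort(sprintf("config field '%s' must lie in [0, 0.1)", p),
            class = "coralba_config_error")
    }
  }
  class(cfg) <- "synth_config"
  cfg
}

sim_month_grid <- function(config) {
  last <- month_index(config$collection_year, config$collection_month)
  first <- last - config$n_years * 12L + 1L
  mi <- seq(first, last)
  tibble(year = index_to_year(mi), month = index_to_month(mi))
}

#' Inject a lagged exponential spike into a monthly forcing
#'
#' Adds `magnitude * exp(-k / decay_months)` at months `event + lag + k`,
#' k >= 0 (a single-month impulse when `decay_months = 0`). Months before
#' the lagged onset are untouched.
#'
#' @param forcing A [monthly_series()].
#' @param event_year,event_month Date of the triggering event.
#' @param magnitude Spike height at onset (forcing units), >= 0.
#' @param lag_months Months between event and forcing onset, >= 0.
#' @param decay_months e-folding decay time of the spike tail, >= 0.
#' @return The forcing with the spike added.
#' @export
inject_spike <- function(forcing, event_year, event_month, magnitude,
                         lag_months = 0, decay_months = 0) {
  assert_monthly(forcing, what = "forcing")
  if (magnitude < 0 || decay_months < 0 || lag_months < 0) {
    abort("magnitude, lag and decay must be non-negative",
          class = "coralba_config_error")
  }
  mi <- ms_index(forcing)
  onset <- month_index(event_year, event_month) + as.integer(lag_months)
  if (onset < mi[1] || onset > mi[length(mi)]) {
    abort("event + lag falls outside the series span",
          class = "coralba_config_error")
  }
  k <- mi - onset
  hit <- k >= 0
  kernel <- numeric(length(mi))
  if (decay_months == 0) {
    kernel[k == 0] <- magnitude
  } else {
    kernel[hit] <- magnitude * exp(-k[hit] / decay_months)
  }
  forcing$value <- forcing$value + kernel
  forcing
}

seasonal_cos <- function(month, peak_month) {
  cos(2 * pi * (month - peak_month) / 12)
}

#' Simulate the monthly environment (SST and seawater Ba/Ca forcing)
#'
#' SST is a cosine annual cycle (warmest August, coolest February) plus
#' Gaussian noise. The seawater Ba/Ca forcing is the baseline plus the
#' piecewise-linear multidecadal trend through the configured knots, a
#' seasonal term peaking in the typhoon season, and the configured lagged
#' exponential spikes.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @return List with `sst` and `ba_sw` monthly series plus a partial `truth`
#'   list (spike peak months, trend knot years, the seasonal forcing term).
#' @export
simulate_environment <- function(config, seed = 1L) {
  grid <- sim_month_grid(config)
  tt <- month_time(grid$year, grid$month)
  if (any(config$ba_trend_knots$year < grid$year[1] - 1 |
            config$ba_trend_knots$year > grid$year[nrow(grid)] + 1)) {
    abort("trend knots fall outside the simulated span",
          class = "coralba_config_error")
  }
  sst_clim <- config$sst_mean +
    config$sst_amplitude * seasonal_cos(grid$month, 8)
  sst_noise <- with_seed_(seed, rnorm(nrow(grid), 0, config$sst_noise))
  if (config$sst_noise == 0) sst_noise <- rep(0, nrow(grid))
  sst <- monthly_series(grid$year, grid$month, sst_clim + sst_noise,
                        units = "degC")

  trend <- approx(config$ba_trend_knots$year + 0.5, config$ba_trend_knots$level,
                  xout = tt, rule = 2)$y
  seasonal <- config$ba_seasonal_amplitude *
    seasonal_cos(grid$month, config$ba_seasonal_peak_month)
  ba <- monthly_series(grid$year, grid$month,
                       config$ba_baseline + trend + seasonal,
                       units = "umol/mol")
  sp <- config$spike_events
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      ba <- inject_spike(ba, sp$year[i], sp$month[i], sp$magnitude[i],
                         sp$lag_months[i], sp$decay_months[i])
    }
  }
  spike_peaks <- if (nrow(sp) > 0) {
    pk <- month_index(sp$year, sp$month) + as.integer(sp$lag_months)
    tibble(event_year = sp$year, event_month = sp$month,
           lag_months = sp$lag_months,
           peak_year = index_to_year(pk), peak_month = index_to_month(pk),
           magnitude = sp$magnitude)
  } else {
    tibble(event_year = integer(), event_month = integer(),
           lag_months = numeric(), peak_year = integer(),
           peak_month = integer(), magnitude = numeric())
  }
  nk <- nrow(config$ba_trend_knots)
  truth <- list(
    spike_peaks = spike_peaks,
    shift_years = config$ba_trend_knots$year[-c(1, nk)],
    seasonal_forcing = tibble(
      month = 1:12,
      value = config$ba_seasonal_amplitude *
        seasonal_cos(1:12, config$ba_seasonal_peak_month)
    )
  )
  list(sst = sst, ba_sw = ba, truth = truth)
}

growth_weights <- function(profile) {
  if (profile == "uniform") {
    rep(1 / 12, 12)
  } else {
    # cooler months (Dec-Mar) grow at ~40% of the summer rate
    w <- 1 + 0.6 * seasonal_cos(1:12, 8)
    w / sum(w)
  }
}

#' Simulate a full virtual coral core
#'
#' Draws per-year extensions, lays skeleton down month by month, maps the
#' monthly environment onto depth by inverting the cumulative growth curve,
#' samples the four proxy profiles (Sr/Ca, Mg/Ca, Ba/Ca, density) at the
#' microsampling interval, and applies multiplicative Gaussian analytical
#' noise at the configured RSDs. Identical (config, seed) pairs give
#' identical output.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @return List of class `synthetic_core` with elements `sr_ca`, `mg_ca`,
#'   `ba_ca`, `density` (depth series) and `truth` (the truth bundle: the
#'   environment, true tie points, true winter-to-winter and calendar-year
#'   extensions, trend-shift years, spike peak months, monthly growth).
#' @export
simulate_core <- function(config, seed = 1L) {
  env <- simulate_environment(config, seed = seed)
  grid <- sim_month_grid(config)
  n <- nrow(grid)
  years <- sort(unique(grid$year))
  sdlog <- config$extension_sdlog
  ext <- with_seed_(seed + 1L, {
    if (sdlog > 0) {
      rlnorm(length(years),
             meanlog = log(config$mean_extension_mm_yr) - sdlog^2 / 2,
             sdlog = sdlog)
    } else {
      rep(config$mean_extension_mm_yr, length(years))
    }
  })
  names(ext) <- years
  w <- growth_weights(config$growth_profile)
  g <- ext[as.character(grid$year)] * w[grid$month]

  min_inc <- min(g)
  if (config$sampling_interval_mm >= min_inc * 12) {
    abort("sampling interval too coarse for the monthly growth increments",
          class = "coralba_resolution_error")
  }

  # depth of each month's midpoint below the living surface (youngest = last)
  above <- rev(cumsum(rev(g))) - g          # skeleton younger than month i
  depth_mid <- above + g / 2
  total_depth <- sum(g)

  sst_v <- env$sst$value
  proxies <- list(
    sr_ca = config$srca_intercept + config$srca_slope * sst_v,
    mg_ca = config$mgca_intercept + config$mgca_slope * sst_v,
    ba_ca = env$ba_sw$value,
    density = config$density_mean +
      config$density_amplitude * seasonal_cos(grid$month, 3)
  )
  rsds <- c(sr_ca = config$rsd_sr, mg_ca = config$rsd_mg,
            ba_ca = config$rsd_ba, density = config$rsd_density)

  d_grid <- seq(0, total_depth, by = config$sampling_interval_mm)
  # depth increases downcore = backwards in time; interpolate on reversed order
  ord <- order(depth_mid)
  sampled <- lapply(proxies, function(v) {
    approx(depth_mid[ord], v[ord], xout = d_grid, rule = 2)$y
  })
  noisy <- with_seed_(seed + 2L, {
    lapply(names(sampled), function(nm) {
      z <- if (rsds[[nm]] > 0) rnorm(length(d_grid)) else numeric(length(d_grid))
      sampled[[nm]] * (1 + rsds[[nm]] * z)
    })
  })
  names(noisy) <- names(sampled)

  tie <- grid |>
    mutate(depth_mm = depth_mid, time = month_time(.data$year, .data$month)) |>
    filter(.data$month %in% c(2L, 8L)) |>
    mutate(kind = if_else(.data$month == 2L, "winter", "summer")) |>
    arrange(.data$depth_mm) |>
    select("depth_mm", "year", "month", "kind", "time")

  # winter-to-winter truth: extension of year Y = depth(Feb Y) - depth(Feb Y+1)
  winter <- tie |> filter(.data$kind == "winter") |> arrange(.data$year)
  ann_ext <- if (nrow(winter) >= 2) {
    tibble(
      year = winter$year[-nrow(winter)],
      extension_mm = winter$depth_mm[-nrow(winter)] - winter$depth_mm[-1]
    )
  } else {
    tibble(year = integer(), extension_mm = numeric())
  }
  cal_ext <- grid |>
    mutate(g = g) |>
    group_by(.data$year) |>
    summarise(extension_mm = sum(.data$g), n_months = dplyr::n(),
              .groups = "drop")

  truth <- c(env["truth"][["truth"]], list(
    sst = env$sst, ba_sw = env$ba_sw,
    tiepoints = tie,
    annual_extension = ann_ext,
    calendar_extension = cal_ext,
    monthly_growth = grid |> mutate(growth_mm = g, depth_mid_mm = depth_mid),
    total_depth_mm = total_depth,
    density_mean = config$density_mean
  ))

  out <- list(
    sr_ca = depth_series(d_grid, noisy$sr_ca, "sr_ca", config$rsd_sr),
    mg_ca = depth_series(d_grid, noisy$mg_ca, "mg_ca", config$rsd_mg),
    ba_ca = depth_series(d_grid, noisy$ba_ca, "ba_ca", config$rsd_ba),
    density = depth_series(d_grid, noisy$density, "density", config$rsd_density),
    truth = truth,
    config = config
  )
  class(out) <- "synthetic_core"
  out
}

#' Simulate estuarine water samples on a Ba-salinity mixing line
#'
#' Samples lie on `ba = intercept + slope * salinity` plus Gaussian noise,
#' with salinities spread from river (0) to open-bay (35) endmembers — the
#' conservative-mixing geometry seen in estuarine barium surveys.
#'
#' @param n Number of samples.
#' @param slope,intercept Mixing-line parameters (nmol/kg per salinity unit;
#'   nmol/kg at salinity 0).
#' @param sigma Measurement noise sd (nmol/kg).
#' @param seed Integer RNG seed.
#' @return Tibble with `site_id`, `salinity`, `ba_nmol_kg`.
#' @export
simulate_water_samples <- function(n = 14, slope = -2.3, intercept = 120,
                                   sigma = 3, seed = 1L) {
  salinity <- seq(0, 35, length.out = n)
  ba <- with_seed_(seed, intercept + slope * salinity + rnorm(n, 0, sigma))
  tibble(
    site_id = sprintf("site_%02d", seq_len(n)),
    salinity = salinity,
    ba_nmol_kg = pmax(ba, 0.1)
  )
}
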