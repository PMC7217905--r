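# Shared fixtures: all synthetic, built in code.

noise_free_config <- function(...) {
  synth_config(extension_sdlog = 0, sst_noise = 0,
               rsd_ba = 0, rsd_sr = 0, rsd_mg = 0, rsd_density = 0, ...)
}

# eight well-separated spikes, each far above the residual noise scale
spikes_eight <- function() {
  tibble::tibble(
    year = c(1972, 1977, 1983, 1988, 1994, 2000, 2006, 2010),
    month = c(9, 6, 8, 10, 7, 9, 8, 10),
    magnitude = c(0.8, 0.9, 0.85, 1.0, 0.9, 0.95, 0.85, 1.5),
    lag_months = c(0, 3, 2, 1, 0, 2, 3, 4),
    decay_months = rep(2, 8)
  )
}

collection <- c(2014, 10)

# chronology for a simulated core: tie points, age model, monthly Ba/Ca
run_chronology <- function(core) {
  tp <- build_tiepoints(
    detect_extrema(core$sr_ca, "maxima"),
    detect_extrema(core$sr_ca, "minima"),
    collection, sst = core$truth$sst
  )
  model <- build_age_model(tp, collection)
  list(tiepoints = tp, model = model,
       ba_monthly = resample_monthly(core$ba_ca, model))
}

# amplitude of a single frequency in a series, by harmonic regression over
# the central portion (avoids edge effects)
fitted_amplitude <- function(values, period_months, trim = 0.2) {
  n <- length(values)
  core <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  i <- core - 1
  X <- cbind(cos(2 * pi * i / period_months), sin(2 * pi * i / period_months))
  b <- coef(lm(values[core] ~ X))
  sqrt(b[2]^2 + b[3]^2)
}

# closed-form Gaussian low-pass gain at a period in months
lowpass_gain <- function(period_months, bw = 0.00137) {
  exp(-log(2) * ((1 / (period_months * 365 / 12)) / bw)^2)
}

make_months <- function(n, start_year = 1968, start_month = 1) {
  mi <- seq(month_index(start_year, start_month), length.out = n)
  list(year = mi %/% 12L, month = mi %% 12L + 1L)
}
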