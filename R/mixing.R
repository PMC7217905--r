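# Barium-salinity endmember mixing: in an estuary, Ba desorbed from
# river-borne sediment gives a high-Ba, low-salinity river endmember that
# mixes conservatively with low-Ba marine water, so dissolved Ba falls
# linearly with salinity. Coral Ba/Ca converts to seawater Ba concentration
# assuming a distribution coefficient of ~1.

#' Fit a Ba-salinity mixing line to water samples
#'
#' Ordinary least squares of Ba (nmol/kg) on practical salinity; the
#' intercept is the zero-salinity (river) endmember and the evaluation at
#' salinity 35 is the marine endmember.
#'
#' @param samples Tibble with `salinity` and `ba_nmol_kg` (see
#'   [read_water_samples()] or [simulate_water_samples()]); n >= 3 with
#'   non-constant salinity.
#' @return A `mixing_fit` object with slope, intercept (and SEs), r, p, n,
#'   `marine_endmember`; has [tidy()] and [glance()] methods.
#' @export
ba_salinity_fit <- function(samples) {
  if (nrow(samples) < 3) {
    abort("need at least 3 water samples", class = "coralba_length_error")
  }
  if (var(samples$salinity) == 0) {
    abort("salinity is constant; mixing line undefined",
          class = "coralba_degenerate_error")
  }
  fit <- lm(ba_nmol_kg ~ salinity, data = samples)
  sm <- summary(fit)$coefficients
  ct <- pearson(samples$salinity, samples$ba_nmol_kg)
  structure(
    list(slope = sm[2, 1], slope_se = sm[2, 2],
         intercept = sm[1, 1], intercept_se = sm[1, 2],
         r = ct$r, p = ct$p, n = nrow(samples),
         marine_endmember = unname(sm[1, 1] + 35 * sm[2, 1]),
         residuals = unname(fit$residuals), salinity = samples$salinity),
    class = "mixing_fit"
  )
}

#' @export
tidy.mixing_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se))
}

#' @export
glance.mixing_fit <- function(x, ...) {
  tibble(r = x$r, p.value = x$p, n = x$n,
         river_endmember = x$intercept, marine_endmember = x$marine_endmember)
}

#' @export
print.mixing_fit <- function(x, ...) {
  cat(sprintf(
    "Ba-salinity mixing fit: Ba = %.2f %+.3f * S (nmol/kg)\n  r = %.3f, p = %.3g, n = %d; marine endmember (S=35) = %.1f nmol/kg\n",
    x$intercept, x$slope, x$r, x$p, x$n, x$marine_endmember))
  invisible(x)
}

#' Convert coral Ba/Ca to seawater Ba concentration
#'
#' With a distribution coefficient of ~1, `Ba_sw (nmol/kg) = Ba/Ca
#' (umol/mol) x Ca_sw (mmol/kg)`; the salinity-35 seawater Ca reference is
#' 10.28 mmol/kg, so 3.8 umol/mol corresponds to ~39.1 nmol/kg.
#'
#' @param ba_ca_coral Coral Ba/Ca in umol/mol (> 0).
#' @param ca_mmol_kg Seawater Ca concentration (mmol/kg).
#' @param d_coeff Distribution coefficient Ba/Ca_coral / Ba/Ca_seawater.
#' @return Seawater Ba in nmol/kg.
#' @export
coral_to_seawater_ba <- function(ba_ca_coral, ca_mmol_kg = 10.28,
                                 d_coeff = 1) {
  if (any(ba_ca_coral <= 0) || ca_mmol_kg <= 0 || d_coeff <= 0) {
    abort("inputs must be positive", class = "coralba_domain_error")
  }
  ba_ca_coral / d_coeff * ca_mmol_kg
}

#' Convert seawater Ba concentration to coral Ba/Ca
#'
#' Inverse of [coral_to_seawater_ba()].
#'
#' @param ba_sw_nmol_kg Seawater Ba in nmol/kg (> 0).
#' @inheritParams coral_to_seawater_ba
#' @return Coral Ba/Ca in umol/mol.
#' @export
seawater_to_coral_ba <- function(ba_sw_nmol_kg, ca_mmol_kg = 10.28,
                                 d_coeff = 1) {
  if (any(ba_sw_nmol_kg <= 0) || ca_mmol_kg <= 0 || d_coeff <= 0) {
    abort("inputs must be positive", class = "coralba_domain_error")
  }
  ba_sw_nmol_kg * d_coeff / ca_mmol_kg
}
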