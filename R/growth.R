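# Annual skeletal growth parameters: extension (distance between successive
# Sr/Ca maxima = winter tie points), annual mean density, and calcification
# rate = extension (cm) x density (g/cm^3); plus their per-period
# correlation with the low-pass Ba/Ca annual means.

#' Annual extension rates from winter tie points
#'
#' Extension of year Y is the depth distance between the winter (Sr/Ca
#' maximum) tie points bounding it: `depth(winter of Y) - depth(winter of
#' Y+1)`, labelled with the calendar year of the deeper (older) tie — the
#' year containing the interval's summer.
#'
#' @param tiepoints Tie-point tibble ([build_tiepoints()]); only `kind ==
#'   "winter"` rows are used.
#' @return Tibble with `year`, `extension_mm`.
#' @export
annual_extension <- function(tiepoints) {
  w <- tiepoints |> filter(.data$kind == "winter") |> arrange(.data$depth_mm)
  if (nrow(w) < 2) {
    abort("need at least two winter tie points",
          class = "coralba_chronology_error")
  }
  if (is.unsorted(rev(w$year), strictly = TRUE)) {
    abort("winter tie years must decrease with depth",
          class = "coralba_chronology_error")
  }
  tibble(
    year = w$year[-1],                       # deeper tie's calendar year
    extension_mm = diff(w$depth_mm)
  ) |> arrange(.data$year)
}

#' Annual mean skeletal density
#'
#' Averages a calibrated density depth profile over the samples whose
#' age-model dates fall within each complete calendar year (time-averaging;
#' incomplete edge years are omitted).
#'
#' @param density A density [depth_series()] (g/cm^3).
#' @param model An `age_model` covering the profile.
#' @param average `"time"` (default) weights samples equally in time;
#'   `"depth"` weights them by the depth increment they represent.
#' @return Tibble with `year`, `density`.
#' @export
annual_density <- function(density, model, average = c("time", "depth")) {
  average <- match.arg(average)
  assert_depth_series(density)
  tt <- predict_time(model, density$depth_mm)
  yr <- floor(tt)
  span <- range(tt)
  complete <- seq(ceiling(span[1]), floor(span[2] - 1e-9))
  complete <- complete[complete + 1 <= span[2] + 1e-9]
  df <- tibble(year = yr, value = density$value, depth = density$depth_mm) |>
    filter(.data$year %in% complete)
  if (nrow(df) == 0) {
    abort("no complete calendar year covered by the density profile",
          class = "coralba_chronology_error")
  }
  if (average == "time") {
    # samples are ~evenly spaced in depth; weight each by the time it spans
    dt <- c(diff(tt), tail(diff(tt), 1))
    df$wt <- abs(dt)[yr %in% complete]
  } else {
    df$wt <- 1
  }
  df |>
    group_by(.data$year) |>
    summarise(density = sum(.data$value * .data$wt) / sum(.data$wt),
              .groups = "drop")
}

#' Annual calcification rates
#'
#' Calcification (g cm^-2 yr^-1) = extension (mm -> cm) x annual mean
#' density. Years missing from either input are dropped with a warning.
#'
#' @param extension Tibble from [annual_extension()].
#' @param density Tibble from [annual_density()].
#' @return Tibble with `year`, `extension_mm`, `density`, `calcification`.
#' @export
calcification_rate <- function(extension, density) {
  if (any(extension$extension_mm <= 0)) {
    abort("extension rates must be positive", class = "coralba_domain_error")
  }
  joined <- inner_join(extension, density, by = "year")
  dropped <- setdiff(union(extension$year, density$year), joined$year)
  if (length(dropped) > 0) {
    warn(sprintf("dropped %d year(s) missing from one input: %s",
                 length(dropped), paste(sort(dropped), collapse = ", ")))
  }
  joined |>
    mutate(calcification = .data$extension_mm / 10 * .data$density) |>
    arrange(.data$year)
}

#' Per-period correlation of growth with the low-pass Ba/Ca
#'
#' Pearson correlation and OLS slope (with standard error) of annual
#' extension and calcification against the annual mean of the low-pass
#' Ba/Ca, separately for the A-period (years before `boundary_year`) and
#' B-period. Periods with fewer than 3 overlapping years are skipped with a
#' warning.
#'
#' @param growth Tibble from [calcification_rate()] (or any tibble with
#'   `year`, `extension_mm`, `calcification`).
#' @param lowpass_annual Tibble with `year`, `value` ([annual_means()] of
#'   the low-pass component).
#' @param boundary_year First year of the B-period.
#' @return Tibble with `period`, `variable`, `r`, `p`, `n`, `slope`,
#'   `slope_se`, `intercept`.
#' @export
growth_vs_lowpass <- function(growth, lowpass_annual, boundary_year = 1996L) {
  joined <- inner_join(growth, lowpass_annual, by = "year") |>
    mutate(period = if_else(.data$year < boundary_year, "A", "B"))
  vars <- c(extension = "extension_mm", calcification = "calcification")
  vars <- vars[unname(vars) %in% names(joined)]
  out <- list()
  for (per in c("A", "B")) {
    sub <- filter(joined, .data$period == per)
    if (nrow(sub) < 3) {
      warn(sprintf("period %s has %d overlapping year(s); skipped",
                   per, nrow(sub)))
      next
    }
    for (v in names(vars)) {
      yv <- sub[[vars[[v]]]]
      ct <- pearson(sub$value, yv)
      fit <- lm(yv ~ value, data = sub)
      sm <- summary(fit)$coefficients
      out[[length(out) + 1]] <- tibble(
        period = per, variable = v,
        r = ct$r, p = ct$p, n = ct$n,
        slope = sm[2, 1], slope_se = sm[2, 2], intercept = sm[1, 1]
      )
    }
  }
  if (length(out) == 0) {
    abort("no period had enough overlapping years",
          class = "coralba_length_error")
  }
  bind_rows(out)
}
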