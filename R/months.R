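# Calendar-month bookkeeping shared by every stage. A month is identified by
# (year, month); its serial index is year*12 + (month-1) so differences are
# lags in months, and its midpoint in fractional years is year + (month-1/2)/12.

#' Serial month index
#'
#' Maps a (year, month) pair to a serial index counted in months, so that
#' differences between indices are time lags in months.
#'
#' @param year Calendar year (integer).
#' @param month Month of year, 1--12.
#' @return Integer serial index.
#' @export
month_index <- function(year, month) {
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' Fractional-year midpoint of a calendar month
#'
#' @inheritParams month_index
#' @return Numeric time in fractional years at the month midpoint.
#' @export
month_time <- function(year, month) {
  year + (month - 0.5) / 12
}

index_to_year <- function(mi) mi %/% 12L
index_to_month <- function(mi) mi %% 12L + 1L

#' Construct a monthly series
#'
#' A monthly series is the pipeline's working representation: one value per
#' calendar month on a contiguous (year, month) grid.
#'
#' @param year,month,value Equal-length vectors; months must be contiguous
#'   once sorted.
#' @param units Unit string attached as an attribute (informational).
#' @return A `monthly_series` tibble with columns `year`, `month`, `value`.
#' @export
monthly_series <- function(year, month, value, units = NULL) {
  stopifnot(length(year) == length(month), length(month) == length(value))
  if (any(month < 1 | month > 12)) {
    abort("month values must be in 1..12", class = "coralba_format_error")
  }
  mi <- month_index(year, month)
  o <- order(mi)
  mi <- mi[o]
  if (anyDuplicated(mi)) {
    abort("duplicated calendar months in series", class = "coralba_format_error")
  }
  if (length(mi) > 1 && any(diff(mi) != 1L)) {
    abort("monthly series has gaps; fill or reject before constructing",
          class = "coralba_gap_error")
  }
  out <- tibble(
    year = index_to_year(mi),
    month = index_to_month(mi),
    value = as.numeric(value[o])
  )
  attr(out, "units") <- units
  class(out) <- c("monthly_series", class(out))
  out
}

ms_index <- function(ms) month_index(ms$year, ms$month)
ms_time <- function(ms) month_time(ms$year, ms$month)

assert_monthly <- function(ms, min_len = 1L, what = "series") {
  if (!all(c("year", "month", "value") %in% names(ms))) {
    abort(paste0(what, " must have year, month, value columns"),
          class = "coralba_format_error")
  }
  mi <- month_index(ms$year, ms$month)
  if (is.unsorted(mi, strictly = TRUE)) {
    abort(paste0(what, " months must be strictly increasing"),
          class = "coralba_format_error")
  }
  if (length(mi) > 1 && any(diff(mi) != 1L)) {
    abort(paste0(what, " has month gaps; filtering needs a contiguous grid"),
          class = "coralba_gap_error")
  }
  if (nrow(ms) < min_len) {
    abort(sprintf("%s needs at least %d months, got %d", what, min_len, nrow(ms)),
          class = "coralba_length_error")
  }
  invisible(ms)
}

#' Construct a depth series
#'
#' Proxy values indexed by depth below the living surface of the core
#' (0 mm = tissue surface at collection; depth increases downcore, hence
#' backwards in time).
#'
#' @param depth_mm Strictly increasing depths in mm.
#' @param value Proxy value at each depth.
#' @param proxy Proxy name, e.g. `"ba_ca"`, `"sr_ca"`, `"mg_ca"`, `"density"`.
#' @param rsd Fractional analytical relative standard deviation (1 sigma),
#'   attached for reference.
#' @return A `depth_series` tibble with columns `depth_mm`, `value`.
#' @export
depth_series <- function(depth_mm, value, proxy = "proxy", rsd = NA_real_) {
  stopifnot(length(depth_mm) == length(value))
  o <- order(depth_mm)
  depth_mm <- as.numeric(depth_mm[o])
  if (anyDuplicated(depth_mm)) {
    abort("duplicated depths in depth series", class = "coralba_format_error")
  }
  out <- tibble(depth_mm = depth_mm, value = as.numeric(value[o]))
  attr(out, "proxy") <- proxy
  attr(out, "rsd") <- rsd
  class(out) <- c("depth_series", class(out))
  out
}

assert_depth_series <- function(ds, min_len = 2L) {
  if (!all(c("depth_mm", "value") %in% names(ds))) {
    abort("depth series must have depth_mm and value columns",
          class = "coralba_format_error")
  }
  if (is.unsorted(ds$depth_mm, strictly = TRUE)) {
    abort("depths must be strictly increasing", class = "coralba_format_error")
  }
  if (nrow(ds) < min_len) {
    abort(sprintf("depth series needs at least %d points", min_len),
          class = "coralba_length_error")
  }
  if (anyNA(ds$value) || anyNA(ds$depth_mm)) {
    abort("depth series contains missing values", class = "coralba_format_error")
  }
  invisible(ds)
}
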