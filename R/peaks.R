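# High-peak detection on the detrended series relative to the mean seasonal
# cycle, and lag-matching of peaks against a documented-event catalogue
# (floods, typhoons, landslides, quarry collapses).

#' Detect high-peaks in a detrended series
#'
#' Candidate months are those where the detrended value exceeds the overall
#' MSC mean plus `k_sigma` times the standard deviation of the residuals
#' about the MSC. Runs of consecutive candidate months collapse to the
#' single highest month (ties break to the earlier month), so no two
#' reported peaks are adjacent.
#'
#' @param detrended A [monthly_series()] (notch component).
#' @param msc The [mean_seasonal_cycle()] of the same decomposition.
#' @param k_sigma Threshold in residual standard deviations above the MSC
#'   mean. The default 0 is the literal "exceeds the MSC mean" rule; raise
#'   it for noisy records.
#' @return Tibble of peaks: `year`, `month`, `value`, `exceedance`.
#' @export
detect_high_peaks <- function(detrended, msc, k_sigma = 0) {
  assert_monthly(detrended, what = "detrended series")
  if (nrow(detrended) == 0) {
    abort("empty series", class = "coralba_length_error")
  }
  msc_mean <- mean(msc$mean)
  resid <- detrended$value - msc$mean[match(detrended$month, msc$month)]
  threshold <- msc_mean + k_sigma * sd(resid)
  cand <- which(detrended$value > threshold)
  if (length(cand) == 0) {
    return(tibble(year = integer(), month = integer(),
                  value = numeric(), exceedance = numeric()))
  }
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  rep_idx <- vapply(runs, function(ix) ix[which.max(detrended$value[ix])],
                    integer(1))
  rep_idx <- sort(unname(rep_idx))
  tibble(
    year = detrended$year[rep_idx],
    month = detrended$month[rep_idx],
    value = detrended$value[rep_idx],
    exceedance = detrended$value[rep_idx] - threshold
  )
}

#' Match detected peaks to a documented-event catalogue
#'
#' Greedy event-first matching: each catalogue event (in date order) takes
#' the earliest unused peak with lag in `[0, max_lag_months]`; a peak
#' matches at most one event.
#'
#' @param peaks Output of [detect_high_peaks()].
#' @param catalog Event catalogue tibble (`year`, `month`, plus any label
#'   columns; see [read_event_catalog()]).
#' @param max_lag_months Largest admissible peak lag behind the event.
#' @return List of class `event_match` with `matches` (event + peak columns
#'   and `lag_months`), `unmatched_events`, `unmatched_peaks`.
#' @export
match_events <- function(peaks, catalog, max_lag_months = 4L) {
  ev <- catalog |> arrange(month_index(.data$year, .data$month))
  pk_mi <- month_index(peaks$year, peaks$month)
  used <- rep(FALSE, length(pk_mi))
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    emi <- month_index(ev$year[i], ev$month[i])
    lag <- pk_mi - emi
    ok <- which(!used & lag >= 0 & lag <= max_lag_months)
    if (length(ok) == 0) next
    j <- ok[which.min(lag[ok])]
    used[j] <- TRUE
    rows[[i]] <- tibble(
      event_year = ev$year[i], event_month = ev$month[i],
      category = if ("category" %in% names(ev)) ev$category[i] else NA_character_,
      label = if ("label" %in% names(ev)) ev$label[i] else NA_character_,
      peak_year = peaks$year[j], peak_month = peaks$month[j],
      peak_value = peaks$value[j], lag_months = lag[j]
    )
  }
  matched_i <- !vapply(rows, is.null, logical(1))
  matches <- if (any(matched_i)) bind_rows(rows[matched_i]) else {
    tibble(event_year = integer(), event_month = integer(),
           category = character(), label = character(),
           peak_year = integer(), peak_month = integer(),
           peak_value = numeric(), lag_months = integer())
  }
  structure(
    list(matches = matches,
         unmatched_events = ev[!matched_i, , drop = FALSE],
         unmatched_peaks = peaks[!used, , drop = FALSE]),
    class = "event_match"
  )
}

#' @export
tidy.event_match <- function(x, ...) x$matches

#' Count peaks in the A- and B-periods
#'
#' Peaks dated before January of `boundary_year` belong to the A-period,
#' later ones to the B-period (the trend-shift convention: A through
#' December 1995, B from January 1996).
#'
#' @param peaks Output of [detect_high_peaks()].
#' @param boundary_year First year of the B-period.
#' @return Tibble with `period` ("A", "B") and `n_peaks`.
#' @export
count_peaks_by_period <- function(peaks, boundary_year = 1996L) {
  cut <- month_index(boundary_year, 1L)
  mi <- month_index(peaks$year, peaks$month)
  tibble(period = c("A", "B"),
         n_peaks = c(sum(mi < cut), sum(mi >= cut)))
}
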