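# Tie-point chronology: Sr/Ca extrema in depth are anchored to SST extrema
# in time (winter tie = Sr/Ca maximum at the coolest month, summer tie =
# minimum at the warmest), assuming constant growth between ties. Before the
# instrumental SST record the coolest/warmest months default to February and
# August.

#' Detect annual extrema in a depth profile
#'
#' Local maxima or minima of a presmoothed profile (centred moving average
#' over about one month of growth), separated by at least
#' `min_separation_mm`. Plateaus resolve to their midpoint; profile
#' endpoints are never extrema.
#'
#' @param series A [depth_series()].
#' @param kind `"maxima"` or `"minima"`.
#' @param min_separation_mm Minimum depth separation between extrema
#'   (default 4.8 mm, six months at the study's mean 9.6 mm/yr extension).
#' @param smooth_mm Presmoothing window width in mm (about one month of
#'   growth by default).
#' @param min_prominence_frac Minimum topographic prominence of an
#'   extremum, as a fraction of the smoothed profile's range. Annual cycles
#'   have prominence near the full seasonal amplitude while analytical
#'   noise bumps sit one to two orders of magnitude lower, so the default
#'   0.1 separates them cleanly.
#' @param refine_mm Half-width of the quadratic vertex refinement window: a
#'   parabola is least-squares fit to the raw profile within this distance
#'   of each detected extremum and the vertex taken as the extremum depth,
#'   averaging analytical noise across the window for sub-sample
#'   localization (about three months of growth by default; 0 disables).
#' @return Tibble with `depth_mm` and the smoothed `value` at each extremum,
#'   sorted by depth.
#' @export
detect_extrema <- function(series, kind = c("maxima", "minima"),
                           min_separation_mm = 4.8, smooth_mm = 0.8,
                           min_prominence_frac = 0.1, refine_mm = 2.4) {
  kind <- match.arg(kind)
  assert_depth_series(series, min_len = 3L)
  d <- series$depth_mm
  y <- series$value
  step <- stats::median(diff(d))
  k <- max(1L, round(smooth_mm / step))
  if (k %% 2L == 0L) k <- k + 1L
  ys <- if (k > 1L) {
    half <- (k - 1L) %/% 2L
    yp <- c(rep(y[1], half), y, rep(y[length(y)], half))
    as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2))[(half + 1):(half + length(y))]
  } else y
  if (kind == "minima") ys <- -ys

  n <- length(ys)
  left <- c(-Inf, ys[-n])
  right <- c(ys[-1], -Inf)
  cand <- which(ys >= left & ys >= right & seq_len(n) > 1L & seq_len(n) < n)
  # collapse plateaus (equal-value adjacent candidates) to their midpoint
  if (length(cand) > 1) {
    grp <- cumsum(c(1L, diff(cand) != 1L | diff(ys[cand]) != 0))
    cand <- vapply(split(cand, grp),
                   function(ix) ix[ceiling(length(ix) / 2)], integer(1))
  }
  # drop plateau members that are not true local extrema vs their run edges
  cand <- cand[ys[cand] > pmin(left[cand], right[cand])]
  if (length(cand) > 0 && min_prominence_frac > 0) {
    prom_min <- min_prominence_frac * diff(range(ys))
    cand <- cand[prominence_at(ys, cand) >= prom_min]
  }
  if (length(cand) == 0) {
    abort("no extrema found in profile", class = "coralba_chronology_error")
  }
  keep <- integer(0)
  for (i in cand[order(ys[cand], decreasing = TRUE)]) {
    if (all(abs(d[i] - d[keep]) >= min_separation_mm)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  depth_out <- d[keep]
  if (refine_mm > 0) {
    yr <- if (kind == "minima") -y else y
    depth_out <- vapply(keep, function(i) {
      win <- which(abs(d - d[i]) <= refine_mm)
      if (length(win) < 5) return(d[i])
      dd <- d[win] - d[i]
      fit <- stats::lm.fit(cbind(1, dd, dd^2), yr[win])
      b <- fit$coefficients
      if (!is.finite(b[3]) || b[3] >= 0) return(d[i])
      vertex <- -b[2] / (2 * b[3])
      if (abs(vertex) > refine_mm) d[i] else d[i] + vertex
    }, numeric(1))
  }
  tibble(depth_mm = depth_out,
         value = (if (kind == "minima") -ys else ys)[keep])
}

prominence_at <- function(ys, idx) {
  # topographic prominence: height above the higher of the two saddle
  # minima reached before meeting a taller point on each side
  n <- length(ys)
  vapply(idx, function(i) {
    lmin <- ys[i]
    j <- i - 1L
    while (j >= 1L && ys[j] <= ys[i]) {
      lmin <- min(lmin, ys[j])
      j <- j - 1L
    }
    if (j < 1L) lmin <- min(ys[1:i])
    rmin <- ys[i]
    j <- i + 1L
    while (j <= n && ys[j] <= ys[i]) {
      rmin <- min(rmin, ys[j])
      j <- j + 1L
    }
    if (j > n) rmin <- min(ys[i:n])
    ys[i] - max(lmin, rmin)
  }, numeric(1))
}

prev_month_of <- function(mi, target_month) {
  # latest month index strictly before mi whose calendar month == target
  back <- (index_to_month(mi) - target_month) %% 12L
  if (back == 0L) back <- 12L
  mi - back
}

latest_month_of <- function(mi, target_month) {
  # latest month index <= mi whose calendar month == target
  mi - (index_to_month(mi) - target_month) %% 12L
}

#' Build tie points from Sr/Ca extrema and an SST record
#'
#' Merges winter (Sr/Ca maxima) and summer (minima) extrema, checks that
#' they alternate downcore, and assigns calendar dates counting back from
#' the collection date: the i-th maximum from the top gets the i-th coolest
#' month, the i-th minimum the i-th warmest. Within the instrumental span
#' the coolest/warmest month of each cycle is taken from the SST record;
#' before it, the climatological months (February/August by default) are
#' used.
#'
#' @param extrema_max,extrema_min Outputs of [detect_extrema()] for maxima
#'   and minima of the Sr/Ca profile.
#' @param collection_date `c(year, month)` of core collection.
#' @param sst Optional instrumental SST [monthly_series()].
#' @param instrumental_start `c(year, month)` from which tie dates must be
#'   anchored in the SST record (default: start of `sst`). A tie whose
#'   nominal date falls on/after this but outside SST coverage is an error.
#' @param coolest_month,warmest_month Climatological fallback months.
#' @return Tibble of tie points: `depth_mm`, `year`, `month`, `kind`, `time`.
#' @export
build_tiepoints <- function(extrema_max, extrema_min, collection_date,
                            sst = NULL, instrumental_start = NULL,
                            coolest_month = 2L, warmest_month = 8L) {
  tp <- bind_rows(
    tibble(depth_mm = extrema_max$depth_mm, kind = "winter"),
    tibble(depth_mm = extrema_min$depth_mm, kind = "summer")
  ) |> arrange(.data$depth_mm)
  if (nrow(tp) == 0) {
    abort("no extrema supplied", class = "coralba_chronology_error")
  }
  if (any(tp$kind[-1] == tp$kind[-nrow(tp)])) {
    abort("maxima and minima must alternate downcore",
          class = "coralba_chronology_error")
  }
  coll <- month_index(collection_date[1], collection_date[2])
  tgt <- function(kind) if (kind == "winter") coolest_month else warmest_month

  mi <- integer(nrow(tp))
  mi[1] <- latest_month_of(coll, tgt(tp$kind[1]))
  if (nrow(tp) > 1) {
    for (j in 2:nrow(tp)) mi[j] <- prev_month_of(mi[j - 1], tgt(tp$kind[j]))
  }

  if (!is.null(sst)) {
    assert_monthly(sst, what = "sst")
    smi <- ms_index(sst)
    inst0 <- if (is.null(instrumental_start)) smi[1] else {
      month_index(instrumental_start[1], instrumental_start[2])
    }
    for (j in seq_along(mi)) {
      if (mi[j] < inst0) next
      win <- which(smi >= mi[j] - 3L & smi <= mi[j] + 3L)
      if (length(win) == 0) {
        abort(sprintf(
          "tie point near %d-%02d falls in the instrumental span but outside SST coverage",
          index_to_year(mi[j]), index_to_month(mi[j])),
          class = "coralba_chronology_error")
      }
      pick <- if (tp$kind[j] == "winter") win[which.min(sst$value[win])] else {
        win[which.max(sst$value[win])]
      }
      mi[j] <- smi[pick]
    }
  }
  if (any(diff(mi) >= 0)) {
    abort("tie-point dates must strictly decrease with depth",
          class = "coralba_chronology_error")
  }
  tp |>
    mutate(year = index_to_year(mi), month = index_to_month(mi),
           time = month_time(.data$year, .data$month)) |>
    select("depth_mm", "year", "month", "kind", "time")
}

#' Build a piecewise-linear depth-to-time age model
#'
#' Linear interpolation between tie points (constant growth rate within each
#' interval). Above the shallowest tie point the first interval's rate is
#' extrapolated, capped at the collection date; below the deepest, the last
#' interval's rate is extrapolated.
#'
#' @param tiepoints Output of [build_tiepoints()] (needs `depth_mm`, `time`).
#' @param collection_date `c(year, month)`.
#' @return An `age_model` object; use [predict_time()] / [predict_depth()].
#' @export
build_age_model <- function(tiepoints, collection_date) {
  if (nrow(tiepoints) < 2) {
    abort("need at least two tie points", class = "coralba_chronology_error")
  }
  tp <- arrange(tiepoints, .data$depth_mm)
  if (any(diff(tp$time) >= 0)) {
    abort("tie-point dates must strictly decrease with depth",
          class = "coralba_chronology_error")
  }
  structure(
    list(depths = tp$depth_mm, times = tp$time,
         collection_time = month_time(collection_date[1], collection_date[2]),
         tiepoints = tp),
    class = "age_model"
  )
}

#' Map depth to calendar time under an age model
#'
#' @param model An [build_age_model()] result.
#' @param depth_mm Depths in mm.
#' @return Calendar time in fractional years (capped at the collection date
#'   above the shallowest tie point).
#' @export
predict_time <- function(model, depth_mm) {
  d <- model$depths
  t <- model$times
  out <- approx(d, t, xout = depth_mm, rule = 2)$y
  k <- length(d)
  r1 <- (t[1] - t[2]) / (d[2] - d[1])       # years per mm, first interval
  rk <- (t[k - 1] - t[k]) / (d[k] - d[k - 1])
  above <- depth_mm < d[1]
  out[above] <- pmin(t[1] + (d[1] - depth_mm[above]) * r1, model$collection_time)
  below <- depth_mm > d[k]
  out[below] <- t[k] - (depth_mm[below] - d[k]) * rk
  out
}

#' Map calendar time to depth under an age model
#'
#' Inverse of [predict_time()] (ignoring the collection-date cap).
#'
#' @inheritParams predict_time
#' @param time Calendar time in fractional years.
#' @return Depth in mm (may be negative for times after the youngest
#'   extrapolated skeleton; callers should range-check).
#' @export
predict_depth <- function(model, time) {
  d <- model$depths
  t <- model$times
  out <- approx(rev(t), rev(d), xout = time, rule = 2)$y
  k <- length(d)
  r1 <- (t[1] - t[2]) / (d[2] - d[1])
  rk <- (t[k - 1] - t[k]) / (d[k] - d[k - 1])
  late <- time > t[1]
  out[late] <- d[1] - (time[late] - t[1]) / r1
  early <- time < t[k]
  out[early] <- d[k] + (t[k] - time[early]) / rk
  out
}

#' Resample a depth profile onto the monthly grid
#'
#' Each month's value is the linear interpolation of the depth profile at
#' the depth the age model assigns to that month's midpoint (the 15th);
#' months mapping outside the profile are omitted.
#'
#' @param series A [depth_series()].
#' @param model An `age_model` covering the profile.
#' @return A [monthly_series()].
#' @export
resample_monthly <- function(series, model) {
  assert_depth_series(series)
  t_young <- predict_time(model, series$depth_mm[1])
  t_old <- predict_time(model, series$depth_mm[nrow(series)])
  mi_lo <- month_index(floor(t_old), 1L) # candidate months, trimmed below
  mi_hi <- month_index(ceiling(t_young), 12L)
  mi <- seq(mi_lo, mi_hi)
  tt <- month_time(index_to_year(mi), index_to_month(mi))
  keep <- tt >= t_old & tt <= t_young
  mi <- mi[keep]
  tt <- tt[keep]
  dd <- predict_depth(model, tt)
  inside <- dd >= series$depth_mm[1] & dd <= series$depth_mm[nrow(series)]
  mi <- mi[inside]
  dd <- dd[inside]
  if (length(mi) == 0) {
    abort("age model and depth profile do not overlap",
          class = "coralba_chronology_error")
  }
  vals <- approx(series$depth_mm, series$value, xout = dd)$y
  monthly_series(index_to_year(mi), index_to_month(mi), vals,
                 units = attr(series, "units"))
}

#' Calibrate a proxy thermometer against instrumental SST
#'
#' Ordinary least squares of the monthly proxy on SST over their overlap
#' (>= 24 months required).
#'
#' @param proxy,sst [monthly_series()] objects.
#' @return A `proxy_calibration` object with slope, intercept, r, p, n and
#'   the overlap span; has [tidy()] and [glance()] methods.
#' @export
calibrate_sst_proxy <- function(proxy, sst) {
  assert_monthly(proxy, what = "proxy")
  assert_monthly(sst, what = "sst")
  joined <- inner_join(
    proxy |> rename(proxy = "value"),
    sst |> rename(sst = "value"),
    by = c("year", "month")
  )
  if (nrow(joined) < 24) {
    abort(sprintf("calibration overlap is %d months; need >= 24", nrow(joined)),
          class = "coralba_calibration_error")
  }
  fit <- lm(proxy ~ sst, data = joined)
  ct <- pearson(joined$sst, joined$proxy)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         slope_se = summary(fit)$coefficients[2, 2],
         r = ct$r, p = ct$p, n = ct$n,
         span = range(ms_time(joined))),
    class = "proxy_calibration"
  )
}

#' @export
tidy.proxy_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(NA_real_, x$slope_se))
}

#' @export
glance.proxy_calibration <- function(x, ...) {
  tibble(r = x$r, p.value = x$p, n = x$n,
         span_start = x$span[1], span_end = x$span[2])
}

#' Reconstruct SST from a calibrated proxy
#'
#' Inverts the linear thermometer: `SST = (proxy - intercept) / slope`.
#'
#' @param proxy A [monthly_series()].
#' @param cal A [calibrate_sst_proxy()] result (slope must be nonzero).
#' @return SST as a [monthly_series()] (deg C).
#' @export
reconstruct_sst <- function(proxy, cal) {
  if (cal$slope == 0) {
    abort("calibration slope is zero; thermometer not invertible",
          class = "coralba_inversion_error")
  }
  monthly_series(proxy$year, proxy$month,
                 (proxy$value - cal$intercept) / cal$slope, units = "degC")
}

#' Growth-disturbance proxy: residual Sr/Ca after removing the SST signal
#'
#' Delta Sr/Ca = measured Sr/Ca minus the calibration's prediction from SST,
#' per overlapping month. Positive excursions flag skeletal growth
#' disturbance (e.g. post-flood cold/turbid water).
#'
#' @param proxy Measured proxy [monthly_series()].
#' @param cal A [calibrate_sst_proxy()] result.
#' @param sst Instrumental SST [monthly_series()].
#' @return A [monthly_series()] of residuals over the overlap.
#' @export
delta_srca <- function(proxy, cal, sst) {
  joined <- inner_join(
    proxy |> rename(proxy = "value"),
    sst |> rename(sst = "value"),
    by = c("year", "month")
  )
  if (nrow(joined) == 0) {
    abort("proxy and SST do not overlap", class = "coralba_chronology_error")
  }
  monthly_series(joined$year, joined$month,
                 joined$proxy - (cal$intercept + cal$slope * joined$sst),
                 units = attr(proxy, "units"))
}
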