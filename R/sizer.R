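# SiZer (SIgnificant ZERo crossings of derivatives): Gaussian-kernel local
# linear regression across a grid of bandwidths; each (bandwidth, time) cell
# is classed by whether the local slope is significantly positive, negative,
# neither, or estimated from too little data. Trend-shift points are read
# off as sign changes of the significant slope.

#' Local linear slope estimates with Gaussian kernel weights
#'
#' At each grid point t the data are fit by weighted least squares with
#' weights `exp(-(x - t)^2 / (2 h^2))`; the local slope, its standard error
#' (from the weighted residual variance and the hat matrix) and the
#' effective sample size `(sum w)^2 / sum w^2` are returned.
#'
#' @param x,y Numeric vectors (e.g. years and annual means), n >= 5.
#' @param bandwidth Kernel bandwidth h in x units.
#' @param grid Evaluation points (default: the observed x).
#' @return Tibble with `grid`, `fit` (local level), `slope`, `se`, `ess`.
#' @export
local_linear_derivative <- function(x, y, bandwidth, grid = x) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "coralba_format_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 5) {
    abort("need at least 5 points", class = "coralba_length_error")
  }
  if (bandwidth <= 0) {
    abort("bandwidth must be positive", class = "coralba_config_error")
  }
  res <- purrr::map(grid, function(t0) {
    w <- exp(-(x - t0)^2 / (2 * bandwidth^2))
    sw <- sum(w)
    if (sw < .Machine$double.eps * length(x)) {
      return(tibble(grid = t0, fit = NA_real_, slope = NA_real_,
                    se = NA_real_, ess = 0))
    }
    X <- cbind(1, x - t0)
    XtW <- t(X * w)
    A <- XtW %*% X                      # X' W X
    if (abs(det(A)) < 1e-12 * sw^2) {
      return(tibble(grid = t0, fit = NA_real_, slope = NA_real_,
                    se = NA_real_, ess = 0))
    }
    Ainv <- solve(A)
    beta <- Ainv %*% (XtW %*% y)
    fitted <- as.numeric(X %*% beta)
    r <- y - fitted
    # residual df = sum(w) - tr(weighted hat matrix) = sum(w) - 2
    df <- max(sw - sum(w * rowSums((X %*% Ainv) * X)), 1)
    sigma2 <- sum(w * r^2) / df
    # Var(beta) = sigma^2 (X'WX)^-1 X'W^2X (X'WX)^-1
    B <- t(X * w^2) %*% X
    V <- sigma2 * (Ainv %*% B %*% Ainv)
    tibble(grid = t0, fit = beta[1], slope = beta[2], se = sqrt(V[2, 2]),
           ess = sw^2 / sum(w^2))
  })
  bind_rows(res)
}

#' Build a SiZer significance map
#'
#' Classifies every (bandwidth, grid-year) cell of an annual series as
#' significantly increasing, significantly decreasing, not significant, or
#' insufficient data (effective sample size below `ess_min`), using
#' pointwise two-sided Gaussian quantiles at level `alpha`.
#'
#' @param annual Tibble with `year` and `value` (e.g. [annual_means()]),
#'   >= 10 years.
#' @param bandwidths Bandwidth grid in years (default 21 log-spaced values
#'   from 2 to 25 years, reflecting the sub-25-year filter widths scanned).
#' @param alpha Pointwise significance level.
#' @param ess_min Minimum effective sample size for a classed cell.
#' @return A `sizer_map` object (grids, class matrix, slope and SE
#'   matrices); has [tidy()] and [autoplot()] methods.
#' @export
sizer_map <- function(annual, bandwidths = default_bandwidths(),
                      alpha = 0.05, ess_min = 5) {
  if (length(bandwidths) == 0) {
    abort("empty bandwidth grid", class = "coralba_config_error")
  }
  annual <- arrange(as_tibble(annual), .data$year)
  if (nrow(annual) < 10) {
    abort("need at least 10 years for a SiZer map",
          class = "coralba_length_error")
  }
  grid <- annual$year
  q <- qnorm(1 - alpha / 2)
  nb <- length(bandwidths)
  cls <- matrix("not_significant", nrow = nb, ncol = length(grid))
  slope <- se <- ess <- matrix(NA_real_, nrow = nb, ncol = length(grid))
  for (i in seq_len(nb)) {
    d <- local_linear_derivative(annual$year, annual$value, bandwidths[i],
                                 grid = grid)
    slope[i, ] <- d$slope
    se[i, ] <- d$se
    ess[i, ] <- d$ess
    lo <- d$slope - q * d$se
    hi <- d$slope + q * d$se
    cls[i, ] <- dplyr::case_when(
      !is.finite(d$slope) | d$ess < ess_min ~ "insufficient",
      lo > 0 ~ "increasing",
      hi < 0 ~ "decreasing",
      TRUE ~ "not_significant"
    )
  }
  structure(
    list(years = grid, bandwidths = bandwidths, classes = cls,
         slope = slope, se = se, ess = ess, alpha = alpha),
    class = "sizer_map"
  )
}

#' Default SiZer bandwidth grid
#'
#' 21 log-spaced bandwidths from 2 to 25 years.
#' @return Numeric vector of bandwidths (years).
#' @export
default_bandwidths <- function() exp(seq(log(2), log(25), length.out = 21))

#' @export
tidy.sizer_map <- function(x, ...) {
  tidyr::expand_grid(bandwidth = x$bandwidths, year = x$years) |>
    mutate(class = as.vector(t(x$classes)),
           slope = as.vector(t(x$slope)),
           se = as.vector(t(x$se)))
}

#' Extract trend-shift points from a SiZer map
#'
#' Scans each bandwidth row for a transition from a significantly
#' increasing to a significantly decreasing class (or vice versa) with only
#' not-significant cells between; the shift is attributed to the interval
#' between the last cell of the old sign and the first of the new.
#' Identical intervals are aggregated across bandwidths; an interval over
#' which both directions occur (at different bandwidths) is flagged
#' ambiguous and should not be used to split the record.
#'
#' @param map A [sizer_map()].
#' @param bandwidth_range Optional `c(min, max)` restriction in years.
#' @return Tibble with `from_year`, `to_year`, `direction`
#'   (`"increase_to_decrease"` / `"decrease_to_increase"`), `n_bandwidths`,
#'   `bw_min`, `bw_max`, `ambiguous`.
#' @export
find_shift_points <- function(map, bandwidth_range = NULL) {
  rows <- seq_along(map$bandwidths)
  if (!is.null(bandwidth_range)) {
    rows <- which(map$bandwidths >= bandwidth_range[1] &
                    map$bandwidths <= bandwidth_range[2])
  }
  recs <- list()
  for (i in rows) {
    cl <- map$classes[i, ]
    sig <- which(cl %in% c("increasing", "decreasing"))
    if (length(sig) < 2) next
    for (j in seq_len(length(sig) - 1)) {
      a <- sig[j]
      b <- sig[j + 1]
      if (cl[a] == cl[b]) next
      between <- if (b > a + 1) cl[(a + 1):(b - 1)] else character(0)
      if (any(between != "not_significant")) next
      recs[[length(recs) + 1]] <- tibble(
        from_year = map$years[a], to_year = map$years[b],
        direction = if (cl[a] == "increasing") "increase_to_decrease" else
          "decrease_to_increase",
        bandwidth = map$bandwidths[i]
      )
    }
  }
  if (length(recs) == 0) {
    return(tibble(from_year = numeric(), to_year = numeric(),
                  direction = character(), n_bandwidths = integer(),
                  bw_min = numeric(), bw_max = numeric(),
                  ambiguous = logical()))
  }
  all <- bind_rows(recs)
  agg <- all |>
    group_by(.data$from_year, .data$to_year, .data$direction) |>
    summarise(n_bandwidths = dplyr::n(), bw_min = min(.data$bandwidth),
              bw_max = max(.data$bandwidth), .groups = "drop")
  both_dir <- agg |>
    count(.data$from_year, .data$to_year) |>
    filter(.data$n > 1) |>
    select("from_year", "to_year")
  agg |>
    mutate(ambiguous = paste(.data$from_year, .data$to_year) %in%
             paste(both_dir$from_year, both_dir$to_year)) |>
    arrange(.data$from_year, .data$direction)
}

#' Consensus shift interval from a SiZer map
#'
#' The unambiguous shift interval supported by the most bandwidths, pooling
#' intervals whose endpoints differ by at most one grid year.
#'
#' @inheritParams find_shift_points
#' @param direction Optional direction filter.
#' @return One-row tibble (or zero rows if no unambiguous shift).
#' @export
consensus_shift <- function(map, bandwidth_range = NULL, direction = NULL) {
  sp <- find_shift_points(map, bandwidth_range) |> filter(!.data$ambiguous)
  if (!is.null(direction)) sp <- filter(sp, .data$direction == !!direction)
  if (nrow(sp) == 0) return(sp)
  # pool near-identical intervals (midpoints within 1 year)
  sp <- sp |> mutate(mid = (.data$from_year + .data$to_year) / 2)
  support <- vapply(seq_len(nrow(sp)), function(i) {
    sum(sp$n_bandwidths[abs(sp$mid - sp$mid[i]) <= 1 &
                          sp$direction == sp$direction[i]])
  }, numeric(1))
  sp[which.max(support), ] |>
    mutate(n_bandwidths = max(support)) |>
    select(-"mid")
}
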