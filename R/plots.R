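# Diagnostic figures, ggplot2 throughout.

#' @export
autoplot.decomposition <- function(object, ...) {
  df <- tidy(object) |>
    mutate(time = month_time(.data$year, .data$month),
           component = factor(.data$component,
                              c("input", "lowpass", "detrended")))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL,
                  title = "Gaussian low-pass / notch decomposition") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$month, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "calendar month", y = "detrended mean ± SE",
                  title = "Mean seasonal cycle") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sizer_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$bandwidth,
                                   fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(
      increasing = "#2166ac", decreasing = "#b2182b",
      not_significant = "#bdbdbd", insufficient = "#f7f7f7")) +
    ggplot2::labs(x = "year", y = "bandwidth (years)",
                  title = "SiZer derivative significance map") +
    ggplot2::theme_minimal()
}

#' Plot detected high-peaks over the detrended series
#'
#' @param detrended The detrended [monthly_series()].
#' @param peaks Output of [detect_high_peaks()].
#' @return A ggplot object.
#' @export
plot_peaks <- function(detrended, peaks) {
  df <- detrended |> mutate(time = month_time(.data$year, .data$month))
  pk <- peaks |> mutate(time = month_time(.data$year, .data$month))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = pk, colour = "#b2182b", size = 1.5) +
    ggplot2::labs(x = "year", y = "detrended value",
                  title = "High-peaks vs mean-seasonal-cycle threshold") +
    ggplot2::theme_minimal()
}
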