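# Tabular I/O. One CSV dialect throughout: comma-separated, UTF-8, header
# row, '.' decimal. Depth tables: depth_mm + one proxy column. Monthly
# tables: year, month, value. Event catalogues: year, month, category, label.
# Water samples: site_id, salinity, ba_nmol_kg.

#' Read a depth-resolved proxy table
#'
#' @param path CSV file with a `depth_mm` column and the named proxy column.
#' @param proxy Name of the proxy column to read (e.g. `"ba_ca"`).
#' @param column_map Optional named character vector renaming file columns to
#'   the expected names, e.g. `c(depth_mm = "Depth", ba_ca = "Ba.Ca")`.
#' @param rsd Fractional analytical RSD recorded on the result.
#' @return A [depth_series()] tibble.
#' @export
read_depth_series <- function(path, proxy, column_map = NULL, rsd = NA_real_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (target in names(column_map)) {
      src <- column_map[[target]]
      if (!src %in% names(df)) {
        abort(sprintf("column '%s' not found in %s", src, path),
              class = "coralba_schema_error")
      }
      names(df)[names(df) == src] <- target
    }
  }
  for (col in c("depth_mm", proxy)) {
    if (!col %in% names(df)) {
      abort(sprintf("required column '%s' missing from %s", col, path),
            class = "coralba_schema_error")
    }
  }
  if (anyDuplicated(df$depth_mm)) {
    abort("duplicated depth values in depth table", class = "coralba_schema_error")
  }
  ds <- depth_series(df$depth_mm, df[[proxy]], proxy = proxy, rsd = rsd)
  assert_depth_series(ds)
  ds
}

#' Read a monthly series table
#'
#' Reads `year, month, value` rows, sorts them, fills isolated gaps of up to
#' `max_gap` months by linear interpolation (each fill is reported via a
#' message), and rejects longer gaps.
#'
#' @param path CSV file with `year`, `month`, `value` columns.
#' @param max_gap Longest run of missing months that will be interpolated.
#' @return A [monthly_series()] tibble.
#' @export
read_monthly_series <- function(path, max_gap = 3L) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("year", "month", "value")) {
    if (!col %in% names(df)) {
      abort(sprintf("required column '%s' missing from %s", col, path),
            class = "coralba_schema_error")
    }
  }
  mi <- month_index(df$year, df$month)
  o <- order(mi)
  mi <- mi[o]
  val <- as.numeric(df$value[o])
  if (anyDuplicated(mi)) {
    abort("duplicated months in monthly table", class = "coralba_schema_error")
  }
  full <- seq(mi[1], mi[length(mi)])
  missing <- setdiff(full, mi)
  if (length(missing) > 0) {
    runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
    too_long <- vapply(runs, length, integer(1)) > max_gap
    if (any(too_long)) {
      abort(sprintf("monthly table has a gap longer than %d months", max_gap),
            class = "coralba_gap_error")
    }
    filled <- approx(mi, val, xout = full)$y
    message(sprintf("filled %d missing month(s) by linear interpolation",
                    length(missing)))
    mi <- full
    val <- filled
  }
  monthly_series(index_to_year(mi), index_to_month(mi), val)
}

#' Read a documented-event catalogue
#'
#' @param path CSV with `year`, `month`, `category`, `label` columns.
#' @return Tibble of events sorted by date.
#' @export
read_event_catalog <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("year", "month", "category", "label")) {
    if (!col %in% names(df)) {
      abort(sprintf("required column '%s' missing from %s", col, path),
            class = "coralba_schema_error")
    }
  }
  df |>
    mutate(year = as.integer(.data$year), month = as.integer(.data$month)) |>
    arrange(month_index(.data$year, .data$month)) |>
    as_tibble()
}

#' Read a water-sample table
#'
#' @param path CSV with `site_id`, `salinity`, `ba_nmol_kg` columns.
#' @return Tibble of validated samples.
#' @export
read_water_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("site_id", "salinity", "ba_nmol_kg")) {
    if (!col %in% names(df)) {
      abort(sprintf("required column '%s' missing from %s", col, path),
            class = "coralba_schema_error")
    }
  }
  if (any(df$salinity < 0 | df$salinity > 40)) {
    abort("salinity outside [0, 40]", class = "coralba_format_error")
  }
  if (any(df$ba_nmol_kg <= 0)) {
    abort("Ba concentrations must be positive", class = "coralba_format_error")
  }
  as_tibble(df)
}

#' Write a tabular result to CSV
#'
#' Full-precision, deterministic column order (as given), header row.
#'
#' @param records Data frame to write.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_csv(as_tibble(records), path, progress = FALSE)
  invisible(records)
}
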