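#' Graded breakpoint tables for air-quality sub-indices
#'
#' A breakpoint table maps pollutant concentration intervals
#' `[c_low, c_high]` to index intervals `[i_low, i_high]` for the standard
#' linear sub-index interpolation, and carries the regulatory standard
#' concentration `s_p` used by the composite air-quality index. The rows
#' must be sorted and contiguous (each row's upper bound equals the next
#' row's lower bound, in both concentration and index units), which makes
#' the interpolated sub-index continuous and non-decreasing.
#'
#' @param pollutant Pollutant identifier (e.g. `"pm25"`).
#' @param rows Numeric matrix or data frame with columns
#'   `c_low, c_high, i_low, i_high`, one row per graded interval.
#' @param s_p Standard concentration for the composite index (annual
#'   secondary standard; daily for CO, 8-hour for O3). Must be positive.
#' @param units Free-text concentration units, recorded for validation.
#' @return A `breakpoint_table`.
#' @seealso [compute_iaqi()], [compute_composite_index()],
#'   [default_breakpoints()]
#' @export
breakpoint_table <- function(pollutant, rows, s_p, units = "ug/m3") {
  stopifnot(is.character(pollutant), length(pollutant) == 1L)
  need <- c("c_low", "c_high", "i_low", "i_high")
  if (is.matrix(rows) && ncol(rows) == 4L && is.null(colnames(rows))) {
    colnames(rows) <- need
  }
  rows <- as.data.frame(rows)
  if (!all(need %in% colnames(rows))) {
    uh_stop("rows must have columns c_low, c_high, i_low, i_high",
            "config_error")
  }
  rows <- rows[need]
  if (nrow(rows) < 1L || !all(vapply(rows, is.numeric, TRUE))) {
    uh_stop("breakpoint rows must be numeric and non-empty", "config_error")
  }
  if (any(rows$c_low >= rows$c_high) || any(rows$i_low >= rows$i_high)) {
    uh_stop("each row needs c_low < c_high and i_low < i_high",
            "config_error")
  }
  if (nrow(rows) > 1L) {
    k <- seq_len(nrow(rows) - 1L)
    if (any(abs(rows$c_high[k] - rows$c_low[k + 1L]) > 1e-9) ||
        any(abs(rows$i_high[k] - rows$i_low[k + 1L]) > 1e-9)) {
      uh_stop("breakpoint rows must be contiguous (sorted, shared endpoints)",
              "config_error")
    }
  }
  if (!is.numeric(s_p) || length(s_p) != 1L || is.na(s_p) || s_p <= 0) {
    uh_stop("`s_p` must be a single positive number", "config_error")
  }
  structure(list(pollutant = pollutant, rows = rows, s_p = s_p,
                 units = units),
            class = "breakpoint_table")
}

#' Per-pollutant air-quality sub-index by breakpoint interpolation
#'
#' Linearly interpolates a monitored concentration between graded
#' breakpoint intervals:
#' \deqn{\mathrm{IAQI} = \frac{I_{high} - I_{low}}{C_{high} - C_{low}}
#'   (C - C_{low}) + I_{low}}
#' using the row whose concentration interval brackets `C`.
#'
#' @param concentration Nonnegative monitored concentration, in the table's
#'   units.
#' @param table A [breakpoint_table()].
#' @return The sub-index value, inside the bracketing row's index interval.
#'   Concentrations above the top row's `c_high` raise an `above_scale`
#'   error carrying the table's maximum index in field `max_index`
#'   (callers decide whether to cap; the CLI caps with a warning).
#' @examples
#' tab <- breakpoint_table("pm25",
#'   rbind(c(0, 35, 0, 50), c(35, 75, 50, 100)), s_p = 35)
#' compute_iaqi(55, tab)  # 75
#' @export
compute_iaqi <- function(concentration, table) {
  stopifnot(inherits(table, "breakpoint_table"))
  check_number(concentration, "concentration")
  if (concentration < 0) {
    uh_stop("concentration must be nonnegative", "domain_error")
  }
  rows <- table$rows
  top <- nrow(rows)
  if (concentration > rows$c_high[top]) {
    uh_stop(sprintf(
      "concentration %g above top breakpoint %g for %s",
      concentration, rows$c_high[top], table$pollutant),
      "above_scale", max_index = rows$i_high[top])
  }
  if (concentration < rows$c_low[1L]) {
    uh_stop(sprintf("concentration %g below the graded scale of %s",
                    concentration, table$pollutant), "domain_error")
  }
  # the top row's upper bound is an inclusive cap
  k <- findInterval(concentration, rows$c_low, rightmost.closed = FALSE)
  k <- min(k, top)
  with(rows[k, ], i_low + (i_high - i_low) * (concentration - c_low) /
                   (c_high - c_low))
}

#' Overall sub-index over a pollutant panel
#'
#' Aggregates per-pollutant sub-indices by the standard convention: the
#' overall index is the maximum sub-index and the pollutant attaining it is
#' the dominant (primary) pollutant.
#'
#' @param panel Named numeric vector of concentrations, names are pollutant
#'   identifiers.
#' @param tables Named list of [breakpoint_table()]s covering the panel.
#' @return List with `value` (max sub-index), `dominant` (pollutant name)
#'   and `sub_indices` (named vector).
#' @export
compute_overall_iaqi <- function(panel, tables) {
  if (length(panel) == 0L) uh_stop("empty pollutant panel", "domain_error")
  if (is.null(names(panel)) || !all(nzchar(names(panel)))) {
    uh_stop("panel must be a named vector", "domain_error")
  }
  missing <- setdiff(names(panel), names(tables))
  if (length(missing)) {
    uh_stop(sprintf("no breakpoint table for: %s",
                    paste(missing, collapse = ", ")), "config_error")
  }
  sub <- vapply(names(panel),
                function(p) compute_iaqi(panel[[p]], tables[[p]]), 0)
  k <- which.max(sub)
  list(value = unname(sub[k]), dominant = names(sub)[k], sub_indices = sub)
}

#' Thermal comfort index
#'
#' Summarises temperature, wind speed and relative humidity into a scalar
#' comfort value; higher is more comfortable. The temperature term
#' `T - 14.3` is corrected by wind speed through the factor
#' `0.0216 * V * (T - 14.3)`, and relative humidity contributes
#' `1 - 0.01 * |70.5 - RH|`. The default `"ratio"` form reads the wind
#' correction as a denominator,
#' \deqn{\mathrm{TCI} = \frac{T - 14.3}{1 + 0.0216\,V\,(T - 14.3)}
#'   + \bigl(1 - 0.01\,|70.5 - \mathrm{RH}|\bigr),}
#' the `"additive"` form sums the three terms instead.
#'
#' @param temperature Air temperature, degrees C.
#' @param wind_speed Wind speed, m/s, nonnegative.
#' @param relative_humidity Relative humidity, percent in `[0, 100]`.
#' @param form Reading of the wind correction, `"ratio"` (default) or
#'   `"additive"`.
#' @param eps Degenerate-denominator guard: with the ratio form the
#'   denominator can vanish for cold, windy conditions; values within `eps`
#'   of zero raise a `degenerate_input` error.
#' @return The comfort value (dimensionless).
#' @examples
#' compute_tci(24.3, 0, 70.5)  # 11: 10/(1+0) + 1
#' @export
compute_tci <- function(temperature, wind_speed, relative_humidity,
                        form = c("ratio", "additive"), eps = 1e-8) {
  form <- match.arg(form)
  check_number(temperature, "temperature")
  check_number(wind_speed, "wind_speed", lo = 0)
  check_number(relative_humidity, "relative_humidity", lo = 0, hi = 100)
  dt <- temperature - 14.3
  humid <- 1 - 0.01 * abs(70.5 - relative_humidity)
  if (form == "additive") {
    return(dt + 0.0216 * wind_speed * dt + humid)
  }
  den <- 1 + 0.0216 * wind_speed * dt
  if (abs(den) < eps) {
    uh_stop("wind-corrected denominator within eps of zero",
            "degenerate_input")
  }
  dt / den + humid
}

#' Noise pollution index
#'
#' Contribution-weighted average decibel level over noise sources,
#' \eqn{\mathrm{NPI} = \sum_i p_i d_i / \sum_i p_i}, where `p_i` is the
#' contribution rate of source `i` and `d_i` its decibel level. The result
#' is bounded by the smallest and largest source level and is invariant to
#' uniform rescaling of the contributions.
#'
#' @param contributions Nonnegative contribution rates `p_i`, summing to a
#'   positive total.
#' @param decibels Source decibel levels `d_i`, nonnegative, same length.
#' @return The weighted-average decibel value.
#' @examples
#' compute_npi(c(1, 3), c(40, 80))  # 70
#' @export
compute_npi <- function(contributions, decibels) {
  stopifnot(is.numeric(contributions), is.numeric(decibels))
  if (length(contributions) == 0L ||
      length(contributions) != length(decibels)) {
    uh_stop("need >= 1 source with matching contributions and decibels",
            "domain_error")
  }
  if (any(contributions < 0) || any(decibels < 0)) {
    uh_stop("contributions and decibels must be nonnegative", "domain_error")
  }
  total <- sum(contributions)
  if (total <= 0) uh_stop("contributions sum to zero", "domain_error")
  sum(contributions * decibels) / total
}

#' Composite air-quality index
#'
#' The dimensionless comprehensive index
#' \eqn{I_{sum} = \sum_p C_p / S_p} over the pollutants present, where
#' `C_p` is the monitored concentration (monthly mean for SO2, NO2, PM10
#' and PM2.5; a specified percentile for CO and O3) and `S_p` the
#' secondary standard concentration. Larger values indicate heavier
#' overall pollution.
#'
#' @inheritParams compute_overall_iaqi
#' @param tables Named list of [breakpoint_table()]s (their `s_p` fields
#'   supply the standards), or a named numeric vector of standards.
#' @return The composite index value.
#' @examples
#' compute_composite_index(c(pm25 = 35, pm10 = 70),
#'                         c(pm25 = 35, pm10 = 70))  # 2
#' @export
compute_composite_index <- function(panel, tables) {
  if (length(panel) == 0L) uh_stop("empty pollutant panel", "domain_error")
  if (any(panel < 0)) uh_stop("negative concentration", "domain_error")
  standards <- if (is.numeric(tables)) tables
               else vapply(tables, function(t) t$s_p, 0)
  missing <- setdiff(names(panel), names(standards))
  if (length(missing)) {
    uh_stop(sprintf("no standard S_p for: %s",
                    paste(missing, collapse = ", ")), "config_error")
  }
  standards <- standards[names(panel)]
  if (any(standards <= 0)) {
    uh_stop("all standards S_p must be positive", "config_error")
  }
  sum(panel / standards)
}

#' @export
print.breakpoint_table <- function(x, ...) {
  cat(sprintf("<breakpoint_table %s (%s), %d rows, s_p = %g>\n",
              x$pollutant, x$units, nrow(x$rows), x$s_p))
  print(x$rows, row.names = FALSE)
  invisible(x)
}
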