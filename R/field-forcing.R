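#' Season calendar for the modeled year
#'
#' Date windows separating the dry and wet seasons of the modeled plot-year.
#' The defaults are the study-site calendar: dry season 8 Feb--26 May 2018
#' and 21 Jan--10 Feb 2019, wet season 27 May 2018--20 Jan 2019. Interval
#' endpoints are inclusive; the windows must be non-overlapping and jointly
#' cover the modeled year.
#'
#' @param dry_windows list of length-2 Date vectors `(start, end)`.
#' @param wet_windows list of length-2 Date vectors `(start, end)`.
#' @return an object of class `season_windows`.
#' @export
season_windows <- function(
    dry_windows = list(as.Date(c("2018-02-08", "2018-05-26")),
                       as.Date(c("2019-01-21", "2019-02-10"))),
    wet_windows = list(as.Date(c("2018-05-27", "2019-01-20")))) {
  all_w <- c(dry_windows, wet_windows)
  days <- sort(do.call(c, lapply(all_w, function(w) seq(w[1], w[2], by = "day"))))
  if (anyDuplicated(days)) tt_stop("bad_windows", "season windows overlap")
  span <- seq(min(days), max(days), by = "day")
  if (length(days) != length(span)) {
    tt_stop("bad_windows", "season windows leave gaps in the modeled year")
  }
  structure(list(dry_windows = dry_windows, wet_windows = wet_windows,
                 start = min(days), end = max(days)),
            class = "season_windows")
}

#' Classify dates into dry or wet season
#'
#' @param dates Date vector.
#' @param windows a [season_windows()] object.
#' @return character vector `"dry"`/`"wet"`.
#' @export
classify_season <- function(dates, windows = season_windows()) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (w in windows$dry_windows) out[date_in(dates, w)] <- "dry"
  for (w in windows$wet_windows) out[date_in(dates, w)] <- "wet"
  if (anyNA(out)) {
    tt_stop("uncovered_date",
            sprintf("date(s) outside all season windows: %s",
                    paste(format(dates[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Diurnal sinusoid parameters
#'
#' The soil-surface diurnal cycle is modeled as a symmetric sinusoid around
#' the daily mean, with daily temperature range a linear function of the
#' daily mean, `range = max(0, alpha + beta * mean)`, peaking at
#' `peak_hour`. Field temperatures are measured in the early afternoon at
#' `measurement_hour` and are inverted through this sinusoid to recover
#' daily means.
#'
#' @param alpha range intercept (deg C); default 8.
#' @param beta range slope per deg C of daily mean; default 0.2.
#' @param peak_hour local hour of the daily maximum; default 14.
#' @param measurement_hour local hour of the field measurement; default 15.
#' @return an object of class `diurnal_params`.
#' @export
diurnal_params <- function(alpha = 8, beta = 0.2, peak_hour = 14,
                           measurement_hour = 15) {
  structure(list(alpha = alpha, beta = beta, peak_hour = peak_hour,
                 measurement_hour = measurement_hour),
            class = "diurnal_params")
}

# Phase factor of the sinusoid at a given hour: 1 at the peak, -1 twelve
# hours away.
diurnal_phase <- function(hour, peak_hour) {
  sin(2 * pi * (hour - peak_hour) / 24 + pi / 2)
}

#' Expand a daily mean into 24 hourly temperatures
#'
#' `T(h) = mean + (range / 2) * sin(2 pi (h - peak_hour) / 24 + pi / 2)` with
#' `range = max(0, alpha + beta * mean)`. The arithmetic mean of the 24
#' values equals the daily mean exactly and the maximum is attained at
#' `peak_hour`.
#'
#' @param daily_mean daily mean temperature (deg C), scalar.
#' @param params a [diurnal_params()] object.
#' @param hours integer hours to evaluate (default 0:23).
#' @return numeric vector of hourly temperatures.
#' @export
expand_diurnal <- function(daily_mean, params = diurnal_params(), hours = 0:23) {
  rng <- max(0, params$alpha + params$beta * daily_mean)
  daily_mean + (rng / 2) * diurnal_phase(hours, params$peak_hour)
}

# Invert one afternoon observation through the sinusoid to the daily mean:
# solve mean + max(0, alpha + beta*mean)/2 * phase(measurement_hour) = obs.
invert_afternoon <- function(observed, params) {
  s <- diurnal_phase(params$measurement_hour, params$peak_hour)
  # monotonicity of the inversion requires 1 + beta*s/2 > 0 on the branch
  # where the range is positive
  if (1 + params$beta * s / 2 <= 0) {
    tt_stop("bad_params",
            sprintf("diurnal inversion is not monotone (beta = %g, phase = %g)",
                    params$beta, s))
  }
  f <- function(m) m + max(0, params$alpha + params$beta * m) / 2 * s - observed
  lo <- observed - abs(params$alpha) - abs(params$beta) * abs(observed) - 60
  hi <- observed + abs(params$alpha) + abs(params$beta) * abs(observed) + 60
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Recover gap-filled daily mean temperatures from afternoon measurements
#'
#' Each afternoon measurement is inverted through the diurnal sinusoid at
#' `measurement_hour` to a daily mean; days between measurement dates are
#' filled by linear interpolation of the daily means (constant
#' extrapolation at the edges of the record).
#'
#' @param dates measurement dates (Date).
#' @param soil_temp_c afternoon temperatures (deg C), one per date.
#' @param params a [diurnal_params()] object.
#' @param out_dates dates at which daily means are wanted; defaults to every
#'   day spanning the measurements.
#' @return data frame with `date`, `temp_mean`, and logical `measured`.
#' @export
derive_daily_means <- function(dates, soil_temp_c, params = diurnal_params(),
                               out_dates = NULL) {
  dates <- as.Date(dates)
  if (length(unique(dates)) < 2L) {
    tt_stop("bad_input", "need measurements on at least 2 distinct dates")
  }
  ord <- order(dates)
  dates <- dates[ord]
  soil_temp_c <- soil_temp_c[ord]
  # average duplicate same-day measurements before inversion
  agg <- tapply(soil_temp_c, dates, mean)
  mdates <- as.Date(names(agg))
  means <- vapply(unname(agg), invert_afternoon, numeric(1), params = params)
  if (is.null(out_dates)) out_dates <- seq(min(mdates), max(mdates), by = "day")
  filled <- stats::approx(as.numeric(mdates), means, xout = as.numeric(out_dates),
                          method = "linear", rule = 2)$y
  data.frame(date = out_dates, temp_mean = filled,
             measured = out_dates %in% mdates)
}

#' DAYCENT-type moisture rate modifier parameters
#'
#' Constants of the dimensionless moisture function used to scale microbial
#' rates, with the published fine-texture calibration
#' `c1 = 0.6, c2 = 1.27, c3 = 0.0012, c4 = 2.84`. By default the water
#' input is interpreted as percent of pore-volume saturation
#' (`s = W / 100`); set `input = "volumetric"` to supply volumetric water
#' content instead, in which case `s = W / (100 * porosity_phi)`.
#'
#' @param porosity_phi soil porosity as a volume fraction (used only in
#'   volumetric mode).
#' @param c1,c2,c3,c4 fitting constants; must satisfy `c3 < c1 < c2`,
#'   `c4 > 0`.
#' @param input `"saturation"` (default) or `"volumetric"`.
#' @return an object of class `moisture_params`.
#' @export
moisture_params <- function(porosity_phi = 0.5, c1 = 0.6, c2 = 1.27,
                            c3 = 0.0012, c4 = 2.84,
                            input = c("saturation", "volumetric")) {
  input <- match.arg(input)
  if (!(c3 < c1 && c1 < c2)) {
    tt_stop("bad_params", sprintf("moisture constants must satisfy c3 < c1 < c2 (got %g, %g, %g)",
                                  c3, c1, c2))
  }
  if (c4 <= 0) tt_stop("bad_params", "c4 must be positive")
  if (input == "volumetric" && !(porosity_phi > 0 && porosity_phi < 1)) {
    tt_stop("bad_params", "porosity_phi must lie in (0, 1)")
  }
  structure(list(porosity_phi = porosity_phi, c1 = c1, c2 = c2, c3 = c3,
                 c4 = c4, input = input),
            class = "moisture_params")
}

#' Moisture rate modifier
#'
#' Dimensionless multiplier `omega in [0, 1]` scaling microbial rates for
#' water limitation, after the DAYCENT decomposition function:
#' \deqn{\omega(s) = \left(\frac{s - c_2}{c_1 - c_2}\right)^{c_4 (c_2 - c_1)/(c_1 - c_3)}
#'   \left(\frac{s - c_3}{c_1 - c_3}\right)^{c_4}}
#' where `s` is relative saturation. `omega = 1` at `s = c1` (moisture
#' optimum), 0 at or below `s = c3`, and the result is clamped to `[0, 1]`.
#'
#' @param moisture moisture values, percent (of saturation, or volumetric if
#'   the params say so) in `[0, 100]`.
#' @param params a [moisture_params()] object.
#' @return numeric vector of modifiers in `[0, 1]`.
#' @export
moisture_modifier <- function(moisture, params = moisture_params()) {
  if (any(moisture < 0 | moisture > 100, na.rm = TRUE)) {
    tt_stop("bad_input", "moisture must lie within [0, 100] percent")
  }
  s <- if (params$input == "volumetric") {
    moisture / (100 * params$porosity_phi)
  } else {
    moisture / 100
  }
  c1 <- params$c1; c2 <- params$c2; c3 <- params$c3; c4 <- params$c4
  e1 <- c4 * (c2 - c1) / (c1 - c3)
  w <- rep(0, length(s))
  ok <- s > c3
  w[ok] <- ((s[ok] - c2) / (c1 - c2))^e1 * ((s[ok] - c3) / (c1 - c3))^c4
  pmin(pmax(w, 0), 1)
}

#' Build hourly forcing for one plot-year
#'
#' Combines the diurnal sinusoid with sparse field records: afternoon
#' temperatures are inverted to daily means, gap-filled, and expanded to 24
#' hourly values per day; moisture is linearly interpolated between
#' measurement days at daily resolution and held constant within each day.
#'
#' @param records data frame with columns `date`, `soil_temp_c`,
#'   `moisture_pct_sat` for a single plot.
#' @param plot_id plot identifier stored in the output.
#' @param params a [diurnal_params()] object.
#' @param windows a [season_windows()] object defining the modeled year.
#' @return a `forcing_hourly` data frame with columns `plot_id`, `date`,
#'   `hour`, `temp_c`, `moisture_pct_sat`, `measured_day`.
#' @export
build_forcing <- function(records, plot_id, params = diurnal_params(),
                          windows = season_windows()) {
  records$date <- as.Date(records$date)
  if (any(records$moisture_pct_sat < 0 | records$moisture_pct_sat > 100)) {
    tt_stop("bad_input", "moisture_pct_sat outside [0, 100]")
  }
  days <- seq(windows$start, windows$end, by = "day")
  dm <- derive_daily_means(records$date, records$soil_temp_c, params,
                           out_dates = days)
  agg_m <- tapply(records$moisture_pct_sat, records$date, mean)
  mdates <- as.Date(names(agg_m))
  moist_daily <- stats::approx(as.numeric(mdates), unname(agg_m),
                               xout = as.numeric(days), rule = 2)$y
  moist_daily <- pmin(pmax(moist_daily, 0), 100)
  n_days <- length(days)
  hours <- rep(0:23, times = n_days)
  rng <- pmax(0, params$alpha + params$beta * dm$temp_mean)
  temp <- rep(dm$temp_mean, each = 24) +
    rep(rng / 2, each = 24) * diurnal_phase(hours, params$peak_hour)
  structure(
    data.frame(plot_id = plot_id,
               date = rep(days, each = 24),
               hour = hours,
               temp_c = temp,
               moisture_pct_sat = rep(moist_daily, each = 24),
               measured_day = rep(dm$measured, each = 24)),
    class = c("forcing_hourly", "data.frame"))
}

# Full-coverage check shared by the climate summary and the integrator.
check_forcing_coverage <- function(forcing, windows) {
  if (length(unique(forcing$plot_id)) != 1L) {
    tt_stop("bad_input", "forcing must contain exactly one plot_id")
  }
  days <- seq(windows$start, windows$end, by = "day")
  tab <- table(factor(as.character(forcing$date), levels = as.character(days)))
  bad <- names(tab)[tab != 24L]
  if (length(bad)) {
    tt_stop("coverage",
            sprintf("forcing does not provide 24 hourly values for %d day(s): %s%s",
                    length(bad), paste(utils::head(bad, 5), collapse = ", "),
                    if (length(bad) > 5) ", ..." else ""))
  }
  invisible(TRUE)
}

#' Summarise the modeled climate of one plot
#'
#' @param forcing a `forcing_hourly` data frame from [build_forcing()].
#' @param windows a [season_windows()] object.
#' @return a one-row data frame with the plot's modeled mean annual soil
#'   temperature (`soil_mat_c`, mean of daily means), maximum hourly
#'   temperature (`soil_maxt_c`), and per-season mean and SD of temperature
#'   and moisture.
#' @export
summarize_plot_climate <- function(forcing, windows = season_windows()) {
  check_forcing_coverage(forcing, windows)
  daily <- tapply(forcing$temp_c, forcing$date, mean)
  season <- classify_season(forcing$date, windows)
  stat <- function(x, s) c(mean = mean(x[season == s]), sd = stats::sd(x[season == s]))
  td <- stat(forcing$temp_c, "dry"); tw <- stat(forcing$temp_c, "wet")
  md <- stat(forcing$moisture_pct_sat, "dry"); mw <- stat(forcing$moisture_pct_sat, "wet")
  data.frame(plot_id = forcing$plot_id[1],
             soil_mat_c = mean(daily),
             soil_maxt_c = max(forcing$temp_c),
             temp_dry_mean = td["mean"], temp_dry_sd = td["sd"],
             temp_wet_mean = tw["mean"], temp_wet_sd = tw["sd"],
             moist_dry_mean = md["mean"], moist_dry_sd = md["sd"],
             moist_wet_mean = mw["mean"], moist_wet_sd = mw["sd"],
             row.names = NULL)
}

#' Read field records from CSV
#'
#' Expects columns `date, plot_id, land_use, treatment, block, soil_temp_c,
#' moisture_pct_sat` with ISO-8601 dates.
#'
#' @param path path to the CSV file.
#' @return a data frame with `date` parsed to Date.
#' @export
read_field_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "plot_id", "land_use", "treatment", "block",
              "soil_temp_c", "moisture_pct_sat")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    tt_stop("bad_input", sprintf("field CSV is missing column(s): %s",
                                 paste(missing, collapse = ", ")))
  }
  df$date <- as.Date(df$date)
  if (any(df$moisture_pct_sat < 0 | df$moisture_pct_sat > 100)) {
    tt_stop("bad_input", "moisture_pct_sat outside [0, 100]")
  }
  if (any(df$soil_temp_c < -10 | df$soil_temp_c > 70)) {
    tt_stop("bad_input", "soil_temp_c outside [-10, 70]")
  }
  df
}
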