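#' Construct a temperature-screening assay
#'
#' Holds the rate observations of one soil x process across the screening
#' temperatures (canonically 0--45 deg C in 5 deg C steps, technical
#' duplicates). Validation enforces the design the two-stage fit needs:
#' at least three distinct temperatures inside the low (linear) range and at
#' least five distinct temperatures overall. Negative measured rates --
#' instrument noise around zero -- are truncated to 0 and counted in the
#' `n_truncated` attribute.
#'
#' @param soil_id soil / plot identifier.
#' @param process process name (see [dk_sqrt()]).
#' @param temperature_c screening temperatures (deg C), one per observation.
#' @param rate measured rates (ug C g-1 dry soil h-1), one per observation.
#' @param replicate positive integer replicate labels.
#' @param low_range temperature range used by the stage-1 validity check.
#' @return an object of class `thermal_assay` with fields `soil_id`,
#'   `process` and a data frame `observations`.
#' @export
thermal_assay <- function(soil_id, process, temperature_c, rate,
                          replicate = 1L, low_range = c(0, 25)) {
  check_process(process)
  n <- length(temperature_c)
  if (length(rate) != n) tt_stop("bad_assay", "temperature_c and rate lengths differ")
  replicate <- rep_len(as.integer(replicate), n)
  if (any(!is.finite(temperature_c)) || any(temperature_c < -10 | temperature_c > 60)) {
    tt_stop("bad_assay", "screening temperatures must be finite and within [-10, 60] deg C")
  }
  if (any(replicate < 1L)) tt_stop("bad_assay", "replicate labels must be >= 1")
  n_trunc <- sum(rate < 0, na.rm = TRUE)
  if (n_trunc > 0) {
    message(sprintf("thermal_assay [%s / %s]: truncated %d negative rate(s) to 0",
                    soil_id, process, n_trunc))
    rate <- pmax(rate, 0)
  }
  if (any(!is.finite(rate))) tt_stop("bad_assay", "rates must be finite")
  temps <- unique(temperature_c)
  if (length(temps) < 5L) {
    tt_stop("sparse_assay",
            sprintf("assay %s / %s has %d distinct temperatures; >= 5 required",
                    soil_id, process, length(temps)))
  }
  n_low <- sum(temps >= low_range[1] & temps <= low_range[2])
  if (n_low < 3L) {
    tt_stop("sparse_assay",
            sprintf("assay %s / %s has %d distinct temperatures in [%g, %g]; >= 3 required",
                    soil_id, process, n_low, low_range[1], low_range[2]))
  }
  structure(
    list(soil_id = soil_id, process = process,
         observations = data.frame(temperature_c = temperature_c,
                                   rate = rate, replicate = replicate)),
    n_truncated = n_trunc,
    class = "thermal_assay")
}

#' Read temperature-screening assays from CSV
#'
#' Expects columns `soil_id, process, temperature_c, replicate, rate`
#' (UTF-8, header required) and returns one [thermal_assay()] per
#' soil x process combination.
#'
#' @param path path to the CSV file.
#' @return a named list of `thermal_assay` objects, names `"<soil_id>.<process>"`.
#' @export
read_assays <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("soil_id", "process", "temperature_c", "replicate", "rate")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    tt_stop("bad_input", sprintf("assay CSV is missing column(s): %s",
                                 paste(missing, collapse = ", ")))
  }
  keys <- split(df, interaction(df$soil_id, df$process, drop = TRUE))
  lapply(keys, function(d) {
    thermal_assay(d$soil_id[1], d$process[1], d$temperature_c, d$rate, d$replicate)
  })
}

#' Stage 1: calibrate the slope and Tmin on the low temperature range
#'
#' Ordinary least squares of `sqrt(rate)` against temperature, restricted to
#' observations inside `low_range`, where the DK model reduces to the plain
#' Ratkowsky line `a (T - Tmin)`. All replicate observations enter
#' individually. Returns the slope `a` and the x-axis intercept
#' `t_min = -intercept / slope`.
#'
#' @param assay a [thermal_assay()].
#' @param low_range temperature interval (deg C), endpoints inclusive.
#' @return list with `a`, `t_min`, and the number of observations used.
#' @export
fit_low_range <- function(assay, low_range = c(0, 25)) {
  obs <- assay$observations
  keep <- obs$temperature_c >= low_range[1] & obs$temperature_c <= low_range[2]
  sub <- obs[keep, , drop = FALSE]
  if (length(unique(sub$temperature_c)) < 3L) {
    tt_stop("sparse_assay",
            sprintf("assay %s / %s: fewer than 3 distinct temperatures in [%g, %g]",
                    assay$soil_id, assay$process, low_range[1], low_range[2]))
  }
  fit <- stats::lm(sqrt(rate) ~ temperature_c, data = sub)
  a <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || a <= 0) {
    tt_stop("degenerate_fit",
            sprintf("assay %s / %s: non-positive low-range slope (%g)",
                    assay$soil_id, assay$process, a))
  }
  list(a = a, t_min = -intercept / a, n = nrow(sub))
}

#' Stage 2: fit the shape parameter and Tmax over the full range
#'
#' With `a` and `t_min` held fixed at their stage-1 values, minimises the
#' residual sum of squares of `sqrt(rate)` against the full DK model over
#' all observations, by bounded quasi-Newton search over `(b, t_max)` from
#' several starting points. R-squared is reported on the sqrt(rate) scale.
#' When the returned `t_max` lies within `bound_tol` of a search bound a
#' `tmax_bound_hit` diagnostic is set (and a degenerate assay with no
#' measurable high-temperature response will land on the upper bound).
#'
#' @param assay a [thermal_assay()].
#' @param a,t_min stage-1 parameters, held fixed.
#' @param b_bounds,tmax_bounds search bounds; `tmax_bounds` defaults to
#'   `(max(T) - 5, 80)`.
#' @param bound_tol proximity (deg C or units of b) that counts as a bound hit.
#' @return list with `b`, `t_max`, `r2`, `sse`, and `diagnostics`.
#' @export
fit_full <- function(assay, a, t_min,
                     b_bounds = c(1e-3, 2), tmax_bounds = NULL,
                     bound_tol = 1e-3) {
  if (!is.finite(a) || a <= 0) tt_stop("bad_traits", "stage-2 fit requires a > 0")
  obs <- assay$observations
  y <- sqrt(obs$rate)
  temp <- obs$temperature_c
  t_obs_max <- max(temp)
  if (is.null(tmax_bounds)) tmax_bounds <- c(t_obs_max - 5, 80)

  sgn <- if (is_growth_process(assay$process)) -1 else 1
  sse_fun <- function(par) {
    mu <- dk_sqrt(temp, a, t_min, par[1], par[2], assay$process)
    sum((y - mu)^2)
  }
  starts <- rbind(c(0.2, t_obs_max + 5),
                  c(0.05, t_obs_max + 2),
                  c(0.5, t_obs_max + 10),
                  c(0.2, min(t_obs_max + 25, tmax_bounds[2])))
  best <- NULL
  dat <- data.frame(temp = temp, y = y)
  for (i in seq_len(nrow(starts))) {
    # Gauss-Newton with bounds; fall back to bounded quasi-Newton on the SSE
    fit <- tryCatch({
      # per-start convergence chatter is not meaningful: several starts are
      # tried, the best is kept, and a quasi-Newton polish follows
      nl <- suppressWarnings(
        stats::nls(y ~ a * (temp - t_min) * (1 + sgn * exp(b * (temp - tmax))),
                   data = dat,
                   start = list(b = starts[i, 1], tmax = starts[i, 2]),
                   algorithm = "port",
                   lower = c(b_bounds[1], tmax_bounds[1]),
                   upper = c(b_bounds[2], tmax_bounds[2]),
                   control = stats::nls.control(maxiter = 500, warnOnly = TRUE)))
      par <- stats::coef(nl)
      list(par = unname(par), value = sum(stats::resid(nl)^2), convergence = 0L)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(starts[i, ], sse_fun, method = "L-BFGS-B",
                     lower = c(b_bounds[1], tmax_bounds[1]),
                     upper = c(b_bounds[2], tmax_bounds[2]),
                     control = list(factr = 10, pgtol = 1e-12, maxit = 1000)),
        error = function(e) NULL)
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (!is.null(best)) {
    polish <- tryCatch(
      stats::optim(best$par, sse_fun, method = "L-BFGS-B",
                   lower = c(b_bounds[1], tmax_bounds[1]),
                   upper = c(b_bounds[2], tmax_bounds[2]),
                   control = list(factr = 10, pgtol = 1e-14, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value < best$value) best <- polish
  }
  if (is.null(best)) {
    tt_stop("fit_failure",
            sprintf("stage-2 optimisation failed for %s / %s",
                    assay$soil_id, assay$process),
            residual_norm = sqrt(sse_fun(starts[1, ])))
  }
  b <- best$par[1]
  t_max <- best$par[2]
  sse <- best$value
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  # Identifiability: if the pure square-root line (the t_max -> Inf limit of
  # both model forms) fits as well as the optimum, the assay carries no
  # information on the high-temperature response; report t_max at its search
  # bound rather than an arbitrary plateau point.
  sse_line <- sum((y - a * (temp - t_min))^2)
  if (sse_line <= sse + max(1e-10, 1e-8 * sst)) {
    t_max <- tmax_bounds[2]
  }
  bound_hit <- (t_max <= tmax_bounds[1] + bound_tol) ||
    (t_max >= tmax_bounds[2] - bound_tol) ||
    (b <= b_bounds[1] + bound_tol) || (b >= b_bounds[2] - bound_tol)
  if (t_max <= t_obs_max - 20) {
    tt_warn("implausible_fit",
            sprintf("fitted t_max (%.1f) lies far below the assay range (max %.1f) for %s / %s",
                    t_max, t_obs_max, assay$soil_id, assay$process))
  }
  list(b = b, t_max = t_max, r2 = r2, sse = sse,
       diagnostics = list(tmax_bound_hit = bound_hit,
                          convergence = best$convergence))
}

#' Two-stage DK Ratkowsky fit
#'
#' Runs [fit_low_range()] then [fit_full()] and assembles a complete
#' [thermal_traits()] object, including the derivative-based critical
#' temperature (Topt or Ttp) and the Q10 index.
#'
#' @param assay a [thermal_assay()].
#' @param low_range stage-1 temperature interval (deg C).
#' @param q10_interval interval for [compute_q10()].
#' @param ... passed on to [fit_full()].
#' @return a `thermal_traits` object.
#' @export
fit_thermal_traits <- function(assay, low_range = c(0, 25),
                               q10_interval = c(10, 20), ...) {
  s1 <- fit_low_range(assay, low_range)
  s2 <- fit_full(assay, s1$a, s1$t_min, ...)
  tr <- thermal_traits(assay$soil_id, assay$process,
                       a = s1$a, t_min = s1$t_min, b = s2$b, t_max = s2$t_max,
                       r2 = s2$r2, low_range = low_range,
                       diagnostics = s2$diagnostics)
  tr$q10 <- compute_q10(tr, q10_interval)
  tr
}

#' Flatten thermal traits to a one-row data frame
#'
#' @param traits a `thermal_traits` object.
#' @return a one-row data frame suitable for `rbind`ing into a traits table.
#' @export
traits_as_row <- function(traits) {
  data.frame(soil_id = traits$soil_id, process = traits$process,
             a = traits$a, b = traits$b,
             t_min = traits$t_min, t_max = traits$t_max,
             t_crit = traits$t_crit, q10 = traits$q10, r2 = traits$r2,
             tmax_bound_hit = isTRUE(traits$diagnostics$tmax_bound_hit))
}
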