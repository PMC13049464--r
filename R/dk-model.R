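#' Dual-kinetics Ratkowsky square-root model
#'
#' The classic Ratkowsky relationship states that the square root of a
#' microbial process rate is linear in temperature above a minimum
#' temperature Tmin. The dual-kinetics (DK) extension multiplies this line
#' by an exponential deviation term that switches on near a maximum
#' temperature Tmax:
#'
#' \deqn{\sqrt{G}(T) = a (T - T_{min}) (1 - e^{b (T - T_{max})})}{
#'       sqrt(G) = a (T - Tmin) (1 - exp(b (T - Tmax)))}
#' for growth (bacterial or fungal), producing a unimodal curve with a
#' high-temperature decline, and
#' \deqn{\sqrt{R}(T) = a (T - T_{min}) (1 + e^{b (T - T_{max})})}{
#'       sqrt(R) = a (T - Tmin) (1 + exp(b (T - Tmax)))}
#' for respiration, producing a monotone curve that accelerates around Tmax.
#'
#' `dk_sqrt` returns the (unclamped) square-root-scale model value; it is the
#' function the fitting routines minimise against observed `sqrt(rate)`.
#'
#' @param temperature_c temperature in degrees Celsius (vectorised).
#' @param a slope of sqrt(rate) versus temperature,
#'   (ug C g-1 h-1)^0.5 per degree C.
#' @param t_min low x-axis intercept of the square-root relationship (deg C).
#' @param b exponential shape parameter (per deg C).
#' @param t_max high-temperature parameter (deg C): x-axis intercept of the
#'   growth curve, acceleration point of the respiration curve.
#' @param process one of `"bacterial_growth"`, `"fungal_growth"`,
#'   `"respiration"`.
#' @return numeric vector of square-root-scale model values (may be negative
#'   outside the biologically meaningful range).
#' @seealso [evaluate_rate()] for the clamped rate-scale curve.
#' @export
dk_sqrt <- function(temperature_c, a, t_min, b, t_max, process) {
  check_process(process)
  sgn <- if (is_growth_process(process)) -1 else 1
  a * (temperature_c - t_min) * (1 + sgn * exp(b * (temperature_c - t_max)))
}

#' Construct a set of thermal traits
#'
#' Bundles the four DK Ratkowsky parameters with derived indices for one
#' soil x process combination. `t_crit` is the optimum temperature (Topt)
#' for growth processes and the tipping point (Ttp) for respiration; both
#' are computed from the derivative condition by
#' [derive_critical_temperature()] when not supplied.
#'
#' @param soil_id identifier of the soil / plot the traits belong to.
#' @param process process name (see [dk_sqrt()]).
#' @param a,t_min,b,t_max DK Ratkowsky parameters (see [dk_sqrt()]).
#' @param t_crit critical temperature (deg C); computed if `NULL`.
#' @param q10 temperature sensitivity over 10--20 deg C; computed if `NULL`.
#' @param r2 goodness of fit on the sqrt(rate) scale, if known.
#' @param low_range temperature range (deg C) used for the stage-1 fit.
#' @param diagnostics optional named list (e.g. `tmax_bound_hit`).
#' @return an object of class `thermal_traits`.
#' @export
thermal_traits <- function(soil_id, process, a, t_min, b, t_max,
                           t_crit = NULL, q10 = NULL, r2 = NA_real_,
                           low_range = c(0, 25), diagnostics = list()) {
  check_process(process)
  if (!is.finite(a) || a <= 0) {
    tt_stop("bad_traits", sprintf("slope a must be positive (got %g) for %s / %s",
                                  a, soil_id, process))
  }
  if (!is.finite(b) || b <= 0) {
    tt_stop("bad_traits", sprintf("shape b must be positive (got %g) for %s / %s",
                                  b, soil_id, process))
  }
  x <- structure(
    list(soil_id = soil_id, process = process,
         a = a, t_min = t_min, b = b, t_max = t_max,
         t_crit = NA_real_, q10 = NA_real_, r2 = r2,
         low_range = low_range, diagnostics = diagnostics),
    class = "thermal_traits")
  x$t_crit <- if (is.null(t_crit)) derive_critical_temperature(x) else t_crit
  if (x$t_min >= x$t_crit) {
    tt_stop("bad_traits",
            sprintf("t_min (%g) must lie below t_crit (%g) for %s / %s",
                    x$t_min, x$t_crit, soil_id, process))
  }
  if (is_growth_process(process) && x$t_crit >= x$t_max) {
    tt_stop("bad_traits",
            sprintf("t_crit (%g) must lie below t_max (%g) for growth process %s / %s",
                    x$t_crit, x$t_max, soil_id, process))
  }
  x$q10 <- if (is.null(q10)) compute_q10(x) else q10
  x
}

#' @export
print.thermal_traits <- function(x, ...) {
  crit_name <- if (is_growth_process(x$process)) "Topt" else "Ttp"
  cat(sprintf("Thermal traits [%s / %s]\n", x$soil_id, x$process))
  cat(sprintf("  a = %.4g  b = %.4g  Tmin = %.2f  Tmax = %.2f\n",
              x$a, x$b, x$t_min, x$t_max))
  cat(sprintf("  %s = %.2f  Q10 = %.3f  R2 = %.4f\n",
              crit_name, x$t_crit, x$q10, x$r2))
  invisible(x)
}

#' Evaluate the fitted rate curve
#'
#' Returns the process rate on the original (squared) scale. Wherever the
#' square-root-scale model is negative -- below `t_min`, or above `t_max`
#' for growth -- the rate is clamped to zero, so the function is total over
#' real temperatures and never produces negative rates in downstream
#' integration.
#'
#' @param traits a [thermal_traits()] object.
#' @param temperature_c temperature(s) in deg C.
#' @return non-negative rate(s) in ug C g-1 dry soil h-1.
#' @export
evaluate_rate <- function(traits, temperature_c) {
  s <- dk_sqrt(temperature_c, traits$a, traits$t_min, traits$b, traits$t_max,
               traits$process)
  pmax(s, 0)^2
}

#' Critical temperature from the derivative condition
#'
#' Finds the temperature at which the derivative of the square-root-scale
#' growth curve vanishes, i.e. the root of
#' \deqn{e^{b (T - T_{max})} (1 + b (T - T_{min})) = 1}
#' in `(t_min, t_max)`. For growth processes this is the optimum temperature
#' Topt. The respiration curve itself is monotone (its derivative has no
#' real root for `b > 0`), so for respiration the same growth-form condition
#' is applied to the fitted respiration parameters, yielding the tipping
#' point Ttp at which the curve departs from square-root behaviour; this is
#' an explicit package policy (see the methods vignette) and can be
#' overridden by supplying `t_crit` to [thermal_traits()].
#'
#' @param traits a `thermal_traits` object (or any list with fields
#'   `b`, `t_min`, `t_max`).
#' @param tol root-finding tolerance in deg C.
#' @return the critical temperature (deg C).
#' @export
derive_critical_temperature <- function(traits, tol = 1e-8) {
  b <- traits$b
  t_min <- traits$t_min
  t_max <- traits$t_max
  if (!is.finite(b) || b <= 0) {
    tt_stop("bad_traits", "derivative condition requires b > 0")
  }
  f <- function(tt) exp(b * (tt - t_max)) * (1 + b * (tt - t_min)) - 1
  lo <- t_min + 1e-9
  hi <- t_max
  if (f(lo) >= 0 || f(hi) <= 0) {
    tt_stop("no_optimum",
            sprintf("no sign change for the derivative condition in (%g, %g)",
                    lo, hi))
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Temperature sensitivity Q10 from the square-root model
#'
#' In the low-temperature (pure Ratkowsky) range the rate is
#' `a^2 (T - Tmin)^2`, so the factor by which it changes across an interval
#' depends only on `t_min`:
#' \deqn{Q_{10} = \left(\frac{T_{hi} - T_{min}}{T_{lo} - T_{min}}\right)^2}
#' with the conventional interval 10--20 deg C.
#'
#' @param traits a `thermal_traits` object (only `t_min` is used).
#' @param interval numeric length-2, the temperature interval in deg C.
#' @return the dimensionless Q10.
#' @export
compute_q10 <- function(traits, interval = c(10, 20)) {
  t_min <- traits$t_min
  if (t_min >= interval[1]) {
    tt_stop("undefined_q10",
            sprintf("Q10 undefined: t_min (%g) is not below the interval lower bound (%g)",
                    t_min, interval[1]))
  }
  ((interval[2] - t_min) / (interval[1] - t_min))^2
}
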