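# Fixtures built in code: noiseless assays on the model curve, and small
# hourly forcing frames assembled by hand.

screen_temps <- seq(0, 45, by = 5)

# Assay whose sqrt(rate) lies exactly on a line (pure Ratkowsky range).
line_assay <- function(a = 0.1, t_min = -5, temps = seq(0, 25, by = 5),
                       scale = 1) {
  rate <- (a * (temps - t_min))^2 * scale
  thermal_assay("line", "bacterial_growth", temps, rate)
}

# Noiseless assay generated from the full DK formula.
noiseless_assay <- function(a = 0.1, t_min = -5, b = 0.25, t_max = 48,
                            process = "bacterial_growth",
                            temps = screen_temps) {
  growth <- process != "respiration"
  s <- pmax(dk_formula(temps, a, t_min, b, t_max, growth), 0)
  thermal_assay("noiseless", process, temps, s^2)
}

# Hand-assembled hourly forcing frame (bypasses build_forcing).
manual_forcing <- function(plot_id, dates, temps, moist) {
  structure(
    data.frame(plot_id = plot_id,
               date = dates, hour = rep(0:23, length.out = length(temps)),
               temp_c = temps, moisture_pct_sat = moist,
               measured_day = TRUE),
    class = c("forcing_hourly", "data.frame"))
}

# Constant-condition forcing covering the full modeled year.
constant_forcing <- function(temp_c, moisture = 60,
                             windows = season_windows()) {
  days <- seq(windows$start, windows$end, by = "day")
  manual_forcing("const", rep(days, each = 24),
                 rep(temp_c, 24 * length(days)),
                 rep(moisture, 24 * length(days)))
}

# A trio of traits sharing one critical temperature, for closed-form budget
# checks.
shared_crit_traits <- function() {
  base <- list(a = 0.1, t_min = -5, b = 0.25, t_max = 48)
  g <- thermal_traits("toy", "bacterial_growth", base$a, base$t_min, base$b, base$t_max)
  f <- thermal_traits("toy", "fungal_growth", base$a, base$t_min, base$b, base$t_max)
  r <- thermal_traits("toy", "respiration", base$a, base$t_min, base$b, base$t_max,
                      t_crit = g$t_crit)
  list(bacterial_growth = g, fungal_growth = f, respiration = r)
}
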