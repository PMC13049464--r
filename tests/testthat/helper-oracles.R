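# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain normal equations, bisection, brute-force
# grids, and literal transcriptions of the model formulas.

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- (sum(y) - slope * sum(x)) / n
  list(slope = slope, intercept = intercept)
}

# Plain bisection root finder.
bisect_oracle <- function(f, lo, hi, tol = 1e-10, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Literal sqrt-scale DK formula (transcribed independently of dk_sqrt).
dk_formula <- function(temp, a, t_min, b, t_max, growth) {
  if (growth) {
    a * (temp - t_min) * (1 - exp(b * (temp - t_max)))
  } else {
    a * (temp - t_min) * (1 + exp(b * (temp - t_max)))
  }
}

# Brute-force grid search for the stage-2 minimum SSE (sqrt scale).
grid_sse_oracle <- function(temp, sqrt_rate, a, t_min, growth,
                            b_grid = seq(0.01, 1, by = 0.001),
                            tmax_grid = seq(40, 70, by = 0.01)) {
  best <- Inf
  best_par <- c(NA, NA)
  for (b in b_grid) {
    mu <- outer(temp, tmax_grid, function(tt, tm) dk_formula(tt, a, t_min, b, tm, growth))
    sse <- colSums((sqrt_rate - mu)^2)
    j <- which.min(sse)
    if (sse[j] < best) {
      best <- sse[j]
      best_par <- c(b, tmax_grid[j])
    }
  }
  list(sse = best, b = best_par[1], t_max = best_par[2])
}

# Direct transcription of the DAYCENT moisture function (saturation input).
omega_oracle <- function(s, c1 = 0.6, c2 = 1.27, c3 = 0.0012, c4 = 2.84) {
  ((s - c2) / (c1 - c2))^(c4 * (c2 - c1) / (c1 - c3)) *
    ((s - c3) / (c1 - c3))^c4
}
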