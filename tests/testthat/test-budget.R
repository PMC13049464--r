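test_that("normalized temperature response is anchored at the critical temperature", {
  tr <- thermal_traits("s", "bacterial_growth", a = 0.1, t_min = -5,
                       b = 0.25, t_max = 48)
  expect_equal(normalized_tau(tr, tr$t_crit), 1)
  temps <- seq(tr$t_min, tr$t_max, length.out = 500)
  expect_true(all(normalized_tau(tr, temps) >= 0 &
                    normalized_tau(tr, temps) <= 1 + 1e-12))
  # composition oracle: tau(20) = rate(20) / rate(t_crit) evaluated by hand
  rate_of <- function(tt) max(dk_formula(tt, 0.1, -5, 0.25, 48, TRUE), 0)^2
  expect_equal(normalized_tau(tr, 20), rate_of(20) / rate_of(tr$t_crit),
               tolerance = 1e-10)
  # respiration tau exceeds 1 above its tipping point
  trr <- thermal_traits("s", "respiration", a = 0.1, t_min = -5,
                        b = 0.25, t_max = 48)
  expect_gt(normalized_tau(trr, trr$t_crit + 10), 1)
})

test_that("constant optimal conditions integrate to the closed-form total", {
  tl <- shared_crit_traits()
  refs <- reference_rates(g_b_ref = 0.5, g_f_ref = 0.3, r_ref = 1.2,
                          bulk_density = 1.1, depth_m = 0.10)
  # T at the shared optimum and moisture at the DAYCENT optimum (omega = 1)
  fc <- constant_forcing(tl$bacterial_growth$t_crit, moisture = 60)
  b <- integrate_annual_budget(fc, tl, refs)
  n_h <- 368 * 24
  area <- 1.1 * 0.10
  expect_equal(b$cum_growth, (0.5 + 0.3) * n_h * area, tolerance = 1e-9)
  # respiration tau at the growth optimum is not 1 (monotone curve), so
  # check against its own normalized value
  tau_r <- normalized_tau(tl$respiration, tl$bacterial_growth$t_crit)
  expect_equal(b$cum_respiration, 1.2 * tau_r * n_h * area, tolerance = 1e-9)
  # CUE identity and the symmetric special case
  expect_equal(b$cue, b$cum_growth / (b$cum_growth + b$cum_respiration),
               tolerance = 1e-12)
})

test_that("a 48-hour toy series equals the hand-computed Riemann sum", {
  tl <- shared_crit_traits()
  refs <- reference_rates(0.5, 0.3, 1.2, bulk_density = 1.0, depth_m = 0.10)
  days <- rep(as.Date(c("2018-03-01", "2018-03-02")), each = 24)
  set.seed(7)
  temps <- runif(48, 5, 45)
  moist <- runif(48, 5, 80)
  fc <- manual_forcing("toy48", days, temps, moist)
  b <- integrate_annual_budget(fc, tl, refs, windows = NULL)
  # independent hourly accumulation from the transcribed formulas
  rate_of <- function(tt, growth, tc) {
    r <- function(x) max(dk_formula(x, 0.1, -5, 0.25, 48, growth), 0)^2
    r(tt) / r(tc)
  }
  tc <- tl$bacterial_growth$t_crit
  g <- r <- 0
  for (h in 1:48) {
    w <- min(max(omega_oracle(moist[h] / 100), 0), 1)
    g <- g + (0.5 * rate_of(temps[h], TRUE, tc) +
                0.3 * rate_of(temps[h], TRUE, tc)) * w
    r <- r + 1.2 * rate_of(temps[h], FALSE, tc) * w
  }
  expect_equal(b$cum_growth, g * 1.0 * 0.10, tolerance = 1e-9)
  expect_equal(b$cum_respiration, r * 1.0 * 0.10, tolerance = 1e-9)
})

test_that("integration is additive over partitions of the year", {
  tl <- shared_crit_traits()
  refs <- reference_rates(0.5, 0.3, 1.2)
  cfg <- synthetic_config()
  fy <- simulate_field_year(cfg, "p", seed = 2)
  fc <- build_forcing(fy, "p")
  full <- integrate_annual_budget(fc, tl, refs)
  cut <- nrow(fc) %/% 3
  parts <- list(fc[1:cut, ], fc[(cut + 1):(2 * cut), ], fc[(2 * cut + 1):nrow(fc), ])
  partial <- lapply(parts, integrate_annual_budget, traits_list = tl,
                    refs = refs, windows = NULL)
  expect_equal(full$cum_growth, sum(vapply(partial, `[[`, 1, "cum_growth")),
               tolerance = 1e-10)
  expect_equal(full$cum_respiration,
               sum(vapply(partial, `[[`, 1, "cum_respiration")),
               tolerance = 1e-10)
})

test_that("doubling reference rates doubles totals and leaves CUE unchanged", {
  tl <- shared_crit_traits()
  fc <- constant_forcing(25, moisture = 40)
  b1 <- integrate_annual_budget(fc, tl, reference_rates(0.5, 0.3, 1.2))
  b2 <- integrate_annual_budget(fc, tl, reference_rates(1.0, 0.6, 2.4))
  expect_equal(b2$cum_growth, 2 * b1$cum_growth, tolerance = 1e-12)
  expect_equal(b2$cum_respiration, 2 * b1$cum_respiration, tolerance = 1e-12)
  expect_equal(b2$cue, b1$cue, tolerance = 1e-12)
  expect_gt(b1$cue, 0); expect_lt(b1$cue, 1)
})

test_that("null treatment yields five identical budgets", {
  tl <- shared_crit_traits()
  refs <- reference_rates(0.5, 0.3, 1.2)
  cfg <- synthetic_config()
  fc <- build_forcing(simulate_field_year(cfg, "c", seed = 4), "c")
  sc <- scenario_decompose(fc, fc, tl, tl, refs)
  expect_equal(nrow(sc), 5)
  expect_setequal(sc$scenario, c("control", "treatment", "temperature_only",
                                 "moisture_only", "adaptation_only"))
  expect_equal(diff(range(sc$cum_growth)), 0, tolerance = 1e-12)
  expect_equal(diff(range(sc$cum_respiration)), 0, tolerance = 1e-12)
})

test_that("a traits-only difference moves only the adaptation scenario", {
  ctl <- shared_crit_traits()
  warm <- lapply(ctl, function(tr) {
    thermal_traits(tr$soil_id, tr$process, tr$a, tr$t_min + 2, tr$b, tr$t_max)
  })
  refs <- reference_rates(0.5, 0.3, 1.2)
  cfg <- synthetic_config()
  fc <- build_forcing(simulate_field_year(cfg, "c", seed = 4), "c")
  sc <- scenario_decompose(fc, fc, ctl, warm, refs)
  g <- function(lbl, col) sc[sc$scenario == lbl, col]
  expect_equal(g("adaptation_only", "cum_respiration"),
               g("treatment", "cum_respiration"), tolerance = 1e-12)
  expect_equal(g("temperature_only", "cum_growth"), g("control", "cum_growth"),
               tolerance = 1e-12)
  expect_equal(g("moisture_only", "cum_growth"), g("control", "cum_growth"),
               tolerance = 1e-12)
})

test_that("scenario budgets re-compose bit-identically from swapped inputs", {
  cfg_c <- synthetic_config(land_use = "crop", treatment = "control")
  cfg_t <- synthetic_config(land_use = "crop", treatment = "otc")
  fc_c <- build_forcing(simulate_field_year(cfg_c, "c", seed = 9), "c")
  fc_t <- build_forcing(simulate_field_year(cfg_t, "t", seed = 9), "t")
  ctl <- shared_crit_traits()
  warm <- lapply(ctl, function(tr) {
    thermal_traits(tr$soil_id, tr$process, tr$a, tr$t_min + 1.5, tr$b,
                   tr$t_max + 0.5)
  })
  refs <- reference_rates(0.5, 0.3, 1.2)
  sc <- scenario_decompose(fc_c, fc_t, ctl, warm, refs)
  # temperature_only: treatment temperatures, control moisture and traits
  swap_t <- fc_t
  swap_t$moisture_pct_sat <- fc_c$moisture_pct_sat
  direct <- integrate_annual_budget(swap_t, ctl, refs)
  expect_identical(sc$cum_respiration[sc$scenario == "temperature_only"],
                   direct$cum_respiration)
  # adaptation_only: control forcing, treatment traits
  direct_a <- integrate_annual_budget(fc_c, warm, refs)
  expect_identical(sc$cum_respiration[sc$scenario == "adaptation_only"],
                   direct_a$cum_respiration)
  expect_identical(sc$cum_growth[sc$scenario == "adaptation_only"],
                   direct_a$cum_growth)
})

test_that("warm-shifted Tmin strictly decreases both cumulative fluxes", {
  ctl <- shared_crit_traits()
  warm <- lapply(ctl, function(tr) {
    thermal_traits(tr$soil_id, tr$process, tr$a, tr$t_min + 2, tr$b, tr$t_max)
  })
  refs <- reference_rates(0.5, 0.3, 1.2)
  cfg <- synthetic_config()
  fc <- build_forcing(simulate_field_year(cfg, "c", seed = 4), "c")
  b_ctl <- integrate_annual_budget(fc, ctl, refs)
  b_warm <- integrate_annual_budget(fc, warm, refs)
  expect_lt(b_warm$cum_growth, b_ctl$cum_growth)
  expect_lt(b_warm$cum_respiration, b_ctl$cum_respiration)
})

test_that("percent reduction is the usual relative difference", {
  expect_equal(round(percent_reduction(199, 127)), 36)
  expect_equal(percent_reduction(10, 10), 0)
  expect_equal(percent_reduction(5, 0), 100)
  expect_error(percent_reduction(0, 1), class = "thermotraits_bad_input")
})

test_that("misaligned forcings are rejected", {
  tl <- shared_crit_traits()
  refs <- reference_rates(0.5, 0.3, 1.2)
  cfg <- synthetic_config()
  fc <- build_forcing(simulate_field_year(cfg, "c", seed = 4), "c")
  expect_error(scenario_decompose(fc, fc[-1, ], tl, tl, refs),
               class = "thermotraits_alignment")
})
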