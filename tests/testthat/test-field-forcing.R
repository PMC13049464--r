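test_that("season classification follows the study calendar with inclusive endpoints", {
  w <- season_windows()
  expect_equal(classify_season(as.Date("2018-03-01"), w), "dry")
  expect_equal(classify_season(as.Date("2018-08-15"), w), "wet")
  # boundary convention: both endpoints belong to their window
  expect_equal(classify_season(as.Date("2018-05-26"), w), "dry")
  expect_equal(classify_season(as.Date("2018-05-27"), w), "wet")
  expect_equal(classify_season(as.Date("2019-01-21"), w), "dry")
  expect_error(classify_season(as.Date("2020-01-01"), w),
               class = "thermotraits_uncovered_date")
})

test_that("season windows must partition the modeled year", {
  days <- seq(season_windows()$start, season_windows()$end, by = "day")
  seasons <- classify_season(days)  # full coverage, no error
  expect_equal(length(seasons), 368)
  expect_setequal(unique(seasons), c("dry", "wet"))
  expect_error(
    season_windows(dry_windows = list(as.Date(c("2018-01-01", "2018-02-01"))),
                   wet_windows = list(as.Date(c("2018-01-20", "2018-03-01")))),
    class = "thermotraits_bad_windows")
  expect_error(
    season_windows(dry_windows = list(as.Date(c("2018-01-01", "2018-02-01"))),
                   wet_windows = list(as.Date(c("2018-02-10", "2018-03-01")))),
    class = "thermotraits_bad_windows")
})

test_that("diurnal expansion preserves the daily mean and the linear range", {
  p <- diurnal_params(alpha = 2, beta = 0.3, peak_hour = 14)
  for (m in c(-3, 10, 25)) {
    temps <- expand_diurnal(m, p)
    expect_equal(mean(temps), m, tolerance = 1e-12)
    expect_equal(max(temps) - min(temps), max(0, 2 + 0.3 * m), tolerance = 1e-12)
    expect_equal(which.max(temps), 15L)  # hour 14 is the 15th element of 0:23
  }
  # hand arithmetic: mean 25, range 2 + 0.3*25 = 9.5, peak value 25 + 4.75
  expect_equal(expand_diurnal(25, p)[15], 29.75)
})

test_that("afternoon inversion matches a bisection oracle and round-trips", {
  p <- diurnal_params(alpha = 2, beta = 0.3, peak_hour = 14, measurement_hour = 15)
  dm <- derive_daily_means(as.Date(c("2018-03-01", "2018-03-02")), c(30, 32), p)
  s <- cos(2 * pi / 24)
  oracle <- bisect_oracle(function(m) m + max(0, 2 + 0.3 * m) / 2 * s - 30,
                          -40, 60, tol = 1e-12)
  expect_equal(dm$temp_mean[1], oracle, tolerance = 1e-8)
  # round trip: expanding the recovered mean reproduces the measurement at 15:00
  expect_equal(expand_diurnal(dm$temp_mean[1], p)[16], 30, tolerance = 1e-6)
})

test_that("a flat diurnal cycle leaves measurements untouched and interpolates linearly", {
  p <- diurnal_params(alpha = 0, beta = 0)
  d <- as.Date(c("2018-03-01", "2018-03-11"))
  dm <- derive_daily_means(d, c(20, 30), p)
  expect_equal(dm$temp_mean[dm$measured], c(20, 30))
  expect_equal(dm$temp_mean[dm$date == as.Date("2018-03-06")], 25)
  expect_error(derive_daily_means(d[1], 20, p), class = "thermotraits_bad_input")
})

test_that("moisture modifier hits its analytic anchors and matches direct evaluation", {
  mp <- moisture_params()
  expect_equal(moisture_modifier(60, mp), 1)        # s = c1 optimum
  expect_equal(moisture_modifier(0.12, mp), 0)      # s = c3 dry limit
  expect_equal(moisture_modifier(0, mp), 0)
  expect_equal(moisture_modifier(30, mp), omega_oracle(0.3), tolerance = 1e-10)
  expect_equal(moisture_modifier(85, mp), min(1, omega_oracle(0.85)), tolerance = 1e-10)
})

test_that("moisture modifier is continuous, unimodal and bounded on (c3, 1]", {
  s <- seq(0.2, 100, by = 0.2)
  w <- moisture_modifier(s)
  expect_true(all(w >= 0 & w <= 1))
  peak <- which.max(w)
  expect_equal(s[peak], 60, tolerance = 0.5)
  expect_true(all(diff(w[seq_len(peak)]) >= -1e-12))
  expect_true(all(diff(w[peak:length(w)]) <= 1e-12))
  # continuity: no jumps larger than the grid scale allows
  expect_lt(max(abs(diff(w))), 0.02)
})

test_that("volumetric input mode rescales by porosity", {
  mp_v <- moisture_params(porosity_phi = 0.5, input = "volumetric")
  # volumetric W = 30 % with phi = 0.5 is s = 0.6 = c1
  expect_equal(moisture_modifier(30, mp_v), 1)
  expect_equal(moisture_modifier(15, mp_v), moisture_modifier(30), tolerance = 1e-12)
  expect_error(moisture_params(c1 = 0.6, c2 = 0.5), class = "thermotraits_bad_params")
  expect_error(moisture_modifier(120), class = "thermotraits_bad_input")
})

test_that("plot climate summary matches hand computation on toy series", {
  w <- season_windows()
  # constant forcing: MAT = maxT = 20
  cs <- summarize_plot_climate(constant_forcing(20), w)
  expect_equal(cs$soil_mat_c, 20)
  expect_equal(cs$soil_maxt_c, 20)
  # two-day toy: daily means {10, 20}, ranges {4, 4} -> MAT 15, maxT 22
  p <- diurnal_params(alpha = 4, beta = 0)
  days <- as.Date(c("2018-03-01", "2018-03-02"))
  temps <- c(expand_diurnal(10, p), expand_diurnal(20, p))
  toy <- manual_forcing("toy", rep(days, each = 24), temps, 50)
  toy_w <- season_windows(dry_windows = list(days), wet_windows = list())
  cs2 <- summarize_plot_climate(toy, toy_w)
  expect_equal(cs2$soil_mat_c, 15)
  expect_equal(cs2$soil_maxt_c, 22)
})

test_that("climate summary rejects duplicate plots and incomplete years", {
  fc <- constant_forcing(20)
  dup <- rbind(fc, transform(fc, plot_id = "other"))
  expect_error(summarize_plot_climate(dup), class = "thermotraits_bad_input")
  expect_error(summarize_plot_climate(fc[-(1:24), ]),
               class = "thermotraits_coverage")
})

test_that("built forcing reproduces the afternoon observation on measurement days", {
  cfg <- synthetic_config(land_use = "forest")
  fy <- simulate_field_year(cfg, "f1", seed = 5)
  p <- diurnal_params()
  fc <- build_forcing(fy, "f1", p)
  expect_equal(nrow(fc), 368 * 24)
  on_day <- fc[fc$date == fy$date[10] & fc$hour == p$measurement_hour, ]
  expect_equal(on_day$temp_c, fy$soil_temp_c[10], tolerance = 1e-6)
  expect_true(all(fc$moisture_pct_sat >= 0 & fc$moisture_pct_sat <= 100))
})
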