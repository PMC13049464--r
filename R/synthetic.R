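#' Configuration for the synthetic-data generator
#'
#' Describes one land-use x treatment combination of the emulated field
#' experiment. The defaults encode the study conditions the analysis is
#' designed for: a warm subtropical cropland and forest with a monomodal
#' rainy season, open-top-chamber (OTC) warming and rain-shelter drought
#' treatments, thermal trait priors spanning the ranges reported for
#' bacterial growth, fungal growth and respiration, and seasonal
#' temperature / moisture statistics (mean +/- SD of the afternoon
#' measurements) with treatment offsets.
#'
#' @param land_use `"crop"` or `"forest"`.
#' @param treatment `"control"`, `"otc"` or `"shelter"`.
#' @param n_blocks number of replicate blocks (default 3).
#' @param seed default base seed for generation.
#' @param assay_noise_cv multiplicative noise CV on the sqrt(rate) scale
#'   (default 0.05).
#' @param ar_rho lag-1 autocorrelation of the field series within a season
#'   (default 0.5; set 0 for white noise).
#' @param trait_priors per-process lists with `t_crit` and `t_max` ranges,
#'   `t_min` ranges per land use, and the rate magnitude at the critical
#'   temperature (`rate_scale`, ug C g-1 h-1).
#' @param trait_climate coupling of Tmin to modeled soil MAT: per-process
#'   `slope` (deg C per deg C), `intercept`, and plot-to-plot `sd`.
#' @param field_effects seasonal means/SDs per land use and treatment
#'   offsets.
#' @param windows a [season_windows()] object for the modeled year.
#' @param diurnal a [diurnal_params()] object used when deriving modeled MAT.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(land_use = "crop", treatment = "control",
                             n_blocks = 3, seed = 1L, assay_noise_cv = 0.05,
                             ar_rho = 0.5,
                             trait_priors = default_trait_priors(),
                             trait_climate = default_trait_climate(),
                             field_effects = default_field_effects(),
                             windows = season_windows(),
                             diurnal = diurnal_params()) {
  stopifnot(land_use %in% c("crop", "forest"),
            treatment %in% c("control", "otc", "shelter"),
            assay_noise_cv >= 0, ar_rho >= 0, ar_rho < 1)
  for (p in processes()) {
    pr <- trait_priors[[p]]
    if (max(pr$t_min[[land_use]]) >= min(pr$t_crit) ||
        max(pr$t_crit) >= max(pr$t_max)) {
      tt_stop("bad_config",
              sprintf("trait prior ranges for %s are not ordered t_min < t_crit < t_max", p))
    }
  }
  structure(list(land_use = land_use, treatment = treatment,
                 n_blocks = n_blocks, seed = seed,
                 assay_noise_cv = assay_noise_cv, ar_rho = ar_rho,
                 trait_priors = trait_priors, trait_climate = trait_climate,
                 field_effects = field_effects, windows = windows,
                 diurnal = diurnal),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_trait_priors <- function() {
  list(
    bacterial_growth = list(
      t_crit = c(33, 38), t_max = c(47, 49),
      t_min = list(crop = c(-4.5, -2.0), forest = c(-7.0, -4.5)),
      rate_scale = 0.5),
    fungal_growth = list(
      t_crit = c(36, 40), t_max = c(47, 50),
      t_min = list(crop = c(-4.0, -1.5), forest = c(-6.5, -4.0)),
      rate_scale = 0.35),
    respiration = list(
      t_crit = c(32, 40), t_max = c(46, 54),
      t_min = list(crop = c(-9.0, -6.5), forest = c(-6.5, -4.0)),
      rate_scale = 2.5))
}

#' @rdname synthetic_config
#' @export
default_trait_climate <- function() {
  list(bacterial_growth = list(slope = 0.25, intercept = -10.5, sd = 0.3),
       fungal_growth = list(slope = 0.25, intercept = -10.0, sd = 0.3),
       respiration = list(slope = -0.10, intercept = -5.0, sd = 0.3),
       mat_range = c(17, 27))
}

#' @rdname synthetic_config
#' @export
default_field_effects <- function() {
  list(
    crop = list(temp = c(dry = 41.8, wet = 26.7), temp_sd = c(dry = 5.2, wet = 5.1),
                moist = c(dry = 6.1, wet = 30.5), moist_sd = c(dry = 4.3, wet = 12.7)),
    forest = list(temp = c(dry = 29.8, wet = 21.9), temp_sd = c(dry = 3.7, wet = 3.4),
                  moist = c(dry = 10.5, wet = 37.2), moist_sd = c(dry = 3.8, wet = 14.0)),
    otc = list(crop_dry_temp_offset = 3.9, forest_dry_temp_offset = 0.9),
    shelter = list(crop_dry_temp_offset = -1.2, forest_wet_moist_mean = 30.4))
}

#' Solve the shape parameter consistent with a target critical temperature
#'
#' Given `t_min`, `t_max` and a desired critical temperature, finds the
#' `b > 0` satisfying the derivative condition
#' `exp(b (t_crit - t_max)) (1 + b (t_crit - t_min)) = 1`. A positive root
#' exists iff `t_crit` lies above the midpoint of `(t_min, t_max)`.
#'
#' @param t_min,t_crit,t_max temperatures (deg C), `t_min < t_crit < t_max`.
#' @return the shape parameter `b` (per deg C).
#' @export
solve_b_for_tcrit <- function(t_min, t_crit, t_max) {
  if (!(t_min < t_crit && t_crit < t_max)) {
    tt_stop("bad_config", "need t_min < t_crit < t_max")
  }
  if (t_crit <= (t_min + t_max) / 2) {
    tt_stop("bad_config",
            sprintf("no b > 0 yields t_crit = %g: it must exceed the (t_min, t_max) midpoint %g",
                    t_crit, (t_min + t_max) / 2))
  }
  g <- function(b) exp(b * (t_crit - t_max)) * (1 + b * (t_crit - t_min)) - 1
  hi <- 1
  while (g(hi) > 0 && hi < 1e3) hi <- hi * 2
  stats::uniroot(g, c(1e-9, hi), tol = 1e-12)$root
}

#' Draw a ground-truth trait set
#'
#' Samples the critical temperature and `t_max` uniformly within the
#' process's prior range, draws `t_min` either from the land-use-dependent
#' range or (when `soil_mat_c` is supplied) around the configured
#' Tmin-vs-MAT line, then solves the shape parameter `b` consistent with the
#' draw via [solve_b_for_tcrit()] and sets the slope `a` so the rate at the
#' critical temperature equals the configured magnitude. When `soil_mat_c`
#' is supplied the position of `t_crit` (and `t_max`) within its prior range
#' also shifts warm with MAT, emulating community-level thermal adaptation.
#'
#' @param config a [synthetic_config()].
#' @param process process name.
#' @param seed integer seed (mixed with land use and process).
#' @param soil_mat_c optional modeled mean annual soil temperature of the
#'   plot, coupling traits to climate.
#' @return a [thermal_traits()] object flagged with `$true = TRUE`.
#' @export
sample_true_traits <- function(config, process, seed = config$seed,
                               soil_mat_c = NULL) {
  check_process(process)
  pr <- config$trait_priors[[process]]
  set.seed(mix_seed(seed, paste(config$land_use, config$treatment, process)))
  in_range <- function(range, pos) range[1] + pos * (range[2] - range[1])
  if (is.null(soil_mat_c)) {
    t_crit <- stats::runif(1, pr$t_crit[1], pr$t_crit[2])
    t_max <- stats::runif(1, max(pr$t_max[1], t_crit + 1), pr$t_max[2])
    t_min <- stats::runif(1, pr$t_min[[config$land_use]][1],
                          pr$t_min[[config$land_use]][2])
  } else {
    tc <- config$trait_climate
    mr <- tc$mat_range
    frac <- min(max((soil_mat_c - mr[1]) / (mr[2] - mr[1]), 0), 1)
    pos <- function() min(max(0.15 + 0.7 * frac + stats::runif(1, -0.15, 0.15), 0), 1)
    t_crit <- in_range(pr$t_crit, pos())
    t_max <- max(in_range(pr$t_max, pos()), t_crit + 1)
    cl <- tc[[process]]
    t_min <- cl$intercept + cl$slope * soil_mat_c + stats::rnorm(1, 0, cl$sd)
  }
  b <- solve_b_for_tcrit(t_min, t_crit, t_max)
  sgn <- if (is_growth_process(process)) -1 else 1
  denom <- (t_crit - t_min) * (1 + sgn * exp(b * (t_crit - t_max)))
  a <- sqrt(pr$rate_scale) / denom
  tr <- thermal_traits(soil_id = paste(config$land_use, config$treatment, sep = "_"),
                       process = process, a = a, t_min = t_min, b = b,
                       t_max = t_max, t_crit = t_crit)
  tr$true <- TRUE
  tr
}

#' Simulate a temperature-screening assay
#'
#' Generates rates at the ten screening temperatures 0--45 deg C (5 deg C
#' steps) from the DK model, applying multiplicative Gaussian noise on the
#' sqrt(rate) scale and truncating negative draws at zero -- the noise
#' structure under which the stage-1 least-squares assumptions hold.
#'
#' @param traits ground-truth [thermal_traits()].
#' @param n_replicates technical replicates per temperature (default 2).
#' @param noise_cv coefficient of variation of the sqrt-scale noise.
#' @param seed integer seed.
#' @param temperatures screening temperatures (deg C).
#' @return a [thermal_assay()] object.
#' @export
simulate_assay <- function(traits, n_replicates = 2, noise_cv = 0.05,
                           seed = 1L, temperatures = seq(0, 45, by = 5)) {
  stopifnot(noise_cv >= 0)
  set.seed(mix_seed(seed, paste("assay", traits$soil_id, traits$process)))
  temp <- rep(temperatures, each = n_replicates)
  repl <- rep(seq_len(n_replicates), times = length(temperatures))
  s_true <- pmax(dk_sqrt(temp, traits$a, traits$t_min, traits$b, traits$t_max,
                         traits$process), 0)
  s_obs <- s_true * (1 + stats::rnorm(length(temp), 0, noise_cv))
  rate <- pmax(s_obs, 0)^2
  thermal_assay(traits$soil_id, traits$process, temp, rate, repl)
}

#' Simulate one plot-year of field records
#'
#' Produces twice-weekly afternoon temperature and moisture records over
#' the modeled year. Values are drawn around the configured per-season
#' means/SDs with lag-1 autocorrelation `ar_rho` within each season, then
#' treatment offsets are applied: OTC warms the dry season (strongly in the
#' open cropland, weakly under the forest canopy) and the rain shelter
#' lowers wet-season moisture in the forest and slightly cools the cropland
#' dry season. Moisture is truncated to [0, 100] percent saturation.
#'
#' @param config a [synthetic_config()].
#' @param plot_id plot identifier (mixed into the seed, so plots differ).
#' @param seed integer base seed.
#' @param block block label stored in the records.
#' @return a data frame of field records (same dialect as
#'   [read_field_records()]).
#' @export
simulate_field_year <- function(config, plot_id, seed = config$seed,
                                block = "B1") {
  set.seed(mix_seed(seed, paste("field", plot_id)))
  w <- config$windows
  all_days <- seq(w$start, w$end, by = "day")
  offsets <- rep(c(0, 3), length.out = 2 * ceiling(length(all_days) / 7))
  weekly <- rep(seq(0, length(all_days) - 1, by = 7), each = 2) + offsets
  dates <- all_days[weekly[weekly < length(all_days)] + 1]
  season <- classify_season(dates, w)

  fe <- config$field_effects[[config$land_use]]
  t_mean <- unname(fe$temp[season]); t_sd <- unname(fe$temp_sd[season])
  m_mean <- unname(fe$moist[season]); m_sd <- unname(fe$moist_sd[season])

  if (config$treatment == "otc") {
    off <- if (config$land_use == "crop") {
      config$field_effects$otc$crop_dry_temp_offset
    } else {
      config$field_effects$otc$forest_dry_temp_offset
    }
    t_mean[season == "dry"] <- t_mean[season == "dry"] + off
  } else if (config$treatment == "shelter") {
    if (config$land_use == "crop") {
      t_mean[season == "dry"] <- t_mean[season == "dry"] +
        config$field_effects$shelter$crop_dry_temp_offset
    } else {
      m_mean[season == "wet"] <- config$field_effects$shelter$forest_wet_moist_mean
    }
  }

  ar1 <- function(n, rho) {
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    if (n > 1) for (i in 2:n) {
      z[i] <- rho * z[i - 1] + sqrt(1 - rho^2) * stats::rnorm(1)
    }
    z
  }
  n <- length(dates)
  temp <- t_mean + t_sd * ar1(n, config$ar_rho)
  moist <- m_mean + m_sd * ar1(n, config$ar_rho)
  data.frame(date = dates, plot_id = plot_id,
             land_use = config$land_use, treatment = config$treatment,
             block = block,
             soil_temp_c = pmin(pmax(temp, -10), 70),
             moisture_pct_sat = pmin(pmax(moist, 0), 100))
}

#' Simulate a complete two-land-use study
#'
#' Generates the full crossed design (2 land uses x 3 treatments x
#' `n_blocks` blocks): per plot a field year, its modeled mean annual soil
#' temperature, ground-truth traits for the three processes coupled to that
#' MAT, and noisy screening assays. The output tables use the same CSV
#' dialects the ingestion functions read.
#'
#' @param seed integer base seed.
#' @param n_blocks blocks per land use x treatment (default 3).
#' @param land_uses,treatments subsets of the design to generate.
#' @param ... passed to [synthetic_config()].
#' @return list with data frames `assays`, `field`, `true_traits`.
#' @export
simulate_study <- function(seed = 1L, n_blocks = 3,
                           land_uses = c("crop", "forest"),
                           treatments = c("control", "otc", "shelter"), ...) {
  assays <- list(); field <- list(); truth <- list()
  for (lu in land_uses) for (tr in treatments) for (bl in seq_len(n_blocks)) {
    config <- synthetic_config(land_use = lu, treatment = tr, seed = seed, ...)
    plot_id <- paste(lu, tr, bl, sep = "_")
    block <- paste0("B", bl)
    fy <- simulate_field_year(config, plot_id, seed = seed, block = block)
    dm <- derive_daily_means(fy$date, fy$soil_temp_c, config$diurnal,
                             out_dates = seq(config$windows$start,
                                             config$windows$end, by = "day"))
    mat <- mean(dm$temp_mean)
    for (p in processes()) {
      tt <- sample_true_traits(config, p, seed = mix_seed(seed, plot_id),
                               soil_mat_c = mat)
      tt$soil_id <- plot_id
      asy <- simulate_assay(tt, n_replicates = 2,
                            noise_cv = config$assay_noise_cv,
                            seed = mix_seed(seed, plot_id))
      obs <- asy$observations
      assays[[length(assays) + 1L]] <-
        data.frame(soil_id = plot_id, process = p,
                   temperature_c = obs$temperature_c,
                   replicate = obs$replicate, rate = obs$rate)
      row <- traits_as_row(tt)
      row$soil_mat_true <- mat
      row$land_use <- lu; row$treatment <- tr; row$block <- block
      truth[[length(truth) + 1L]] <- row
    }
    field[[length(field) + 1L]] <- fy
  }
  list(assays = do.call(rbind, assays),
       field = do.call(rbind, field),
       true_traits = do.call(rbind, truth))
}
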