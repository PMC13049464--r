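#' Pipeline run configuration
#'
#' Collects every knob of the analysis: input paths (or synthetic-data
#' settings), the diurnal and moisture parameters, the season calendar, the
#' soil properties for per-area conversion, fitting ranges, output
#' directory and seed. Accepts a YAML or JSON file via `from_file`.
#'
#' @param assay_csv,field_csv paths to input tables; `NULL` to generate
#'   synthetic inputs instead.
#' @param synthetic logical; generate inputs with [simulate_study()].
#' @param seed integer seed for all randomness.
#' @param output_dir directory the run writes into.
#' @param diurnal a [diurnal_params()] object.
#' @param moisture a [moisture_params()] object.
#' @param windows a [season_windows()] object.
#' @param bulk_density,depth_m per-area conversion (see [reference_rates()]).
#' @param low_range stage-1 fitting range (deg C).
#' @param q10_interval interval for [compute_q10()].
#' @param n_blocks blocks per cell when generating synthetic data.
#' @param from_file optional path to a YAML/JSON config; scalar fields in
#'   the file override the defaults.
#' @return an object of class `run_config`.
#' @export
run_config <- function(assay_csv = NULL, field_csv = NULL, synthetic = TRUE,
                       seed = 1L, output_dir = tempfile("thermotraits_run_"),
                       diurnal = diurnal_params(),
                       moisture = moisture_params(),
                       windows = season_windows(),
                       bulk_density = 1.1, depth_m = 0.10,
                       low_range = c(0, 25), q10_interval = c(10, 20),
                       n_blocks = 3, from_file = NULL) {
  cfg <- list(assay_csv = assay_csv, field_csv = field_csv,
              synthetic = synthetic, seed = as.integer(seed),
              output_dir = output_dir, diurnal = diurnal,
              moisture = moisture, windows = windows,
              bulk_density = bulk_density, depth_m = depth_m,
              low_range = low_range, q10_interval = q10_interval,
              n_blocks = n_blocks)
  if (!is.null(from_file)) {
    raw <- if (grepl("\\.json$", from_file)) {
      jsonlite::read_json(from_file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(from_file)
    }
    for (nm in intersect(names(raw), c("assay_csv", "field_csv", "synthetic",
                                       "seed", "output_dir", "bulk_density",
                                       "depth_m", "n_blocks"))) {
      cfg[[nm]] <- raw[[nm]]
    }
    if (!is.null(raw$diurnal)) cfg$diurnal <- do.call(diurnal_params, raw$diurnal)
    if (!is.null(raw$moisture)) cfg$moisture <- do.call(moisture_params, raw$moisture)
    if (!is.null(raw$low_range)) cfg$low_range <- as.numeric(raw$low_range)
    if (!is.null(raw$q10_interval)) cfg$q10_interval <- as.numeric(raw$q10_interval)
  }
  if (!is.null(cfg$assay_csv) || !is.null(cfg$field_csv)) cfg$synthetic <- FALSE
  structure(cfg, class = "run_config")
}

#' Ordinary least-squares regression of a thermal trait on plot climate
#'
#' Regresses one trait (e.g. `t_min` of bacterial growth) against a plot
#' climate predictor (modeled soil MAT or maximum soil temperature) across
#' plots, pooling treatments. Reports the slope (deg C trait per deg C
#' climate), intercept, R-squared, the two-sided p-value for slope = 0, and
#' the number of plots.
#'
#' @param traits_table data frame with `soil_id`, `process`, and trait
#'   columns (as built by [traits_as_row()]).
#' @param climate_table data frame with `plot_id` and climate columns (as
#'   built by [summarize_plot_climate()]).
#' @param trait trait column name (e.g. `"t_min"`).
#' @param process process whose traits are regressed.
#' @param predictor climate column name (default `"soil_mat_c"`).
#' @return a one-row data frame with `trait`, `process`, `predictor`,
#'   `slope`, `intercept`, `r2`, `p_value`, `n`.
#' @export
trait_climate_regression <- function(traits_table, climate_table,
                                     trait = "t_min",
                                     process = "bacterial_growth",
                                     predictor = "soil_mat_c") {
  tt <- traits_table[traits_table$process == process, , drop = FALSE]
  merged <- merge(tt, climate_table, by.x = "soil_id", by.y = "plot_id")
  y <- merged[[trait]]
  x <- merged[[predictor]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    tt_stop("bad_input", sprintf("need >= 3 plots with both %s and %s", trait, predictor))
  }
  if (stats::sd(x) == 0) {
    tt_stop("degenerate_regression",
            sprintf("predictor %s has zero variance", predictor))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(trait = trait, process = process, predictor = predictor,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r2 = sm$r.squared,
             p_value = sm$coefficients[2, 4],
             n = length(x))
}

# Pair every treated plot with the control plot of the same land use and
# block, for scenario decomposition.
pair_with_control <- function(plots) {
  treated <- plots[plots$treatment != "control", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(treated))) {
    ctl <- plots$plot_id[plots$treatment == "control" &
                           plots$land_use == treated$land_use[i] &
                           plots$block == treated$block[i]]
    if (length(ctl) == 1L) {
      out[[length(out) + 1L]] <- data.frame(control = ctl,
                                            treatment_plot = treated$plot_id[i],
                                            land_use = treated$land_use[i],
                                            treatment = treated$treatment[i],
                                            block = treated$block[i])
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: (1) trait fitting for every soil x process assay, (2)
#' hourly forcing and climate summaries per plot, (3) annual budgets per
#' plot, (4) counterfactual scenario decomposition of every treated plot
#' against the control of its block, and (5) trait-vs-climate regressions.
#' All tables are written as CSV into `config$output_dir` together with a
#' JSON manifest and a log; the run is deterministic given the config and
#' seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the tables `traits`, `climate`,
#'   `budgets`, `scenarios`, `regressions` and the output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(name, paste("FAILED:", conditionMessage(e)))
      tt_stop("stage_failure", sprintf("stage '%s' failed: %s", name,
                                       conditionMessage(e)))
    })
  }

  # --- inputs --------------------------------------------------------------
  inputs <- stage("ingest", {
    if (config$synthetic) {
      study <- simulate_study(seed = config$seed, n_blocks = config$n_blocks,
                              windows = config$windows,
                              diurnal = config$diurnal)
      log_line("ingest", sprintf("synthetic study, seed %d", config$seed))
      study
    } else {
      list(assays = utils::read.csv(config$assay_csv, stringsAsFactors = FALSE),
           field = read_field_records(config$field_csv),
           true_traits = NULL)
    }
  })
  field <- inputs$field
  field$date <- as.Date(field$date)
  plots <- unique(field[, c("plot_id", "land_use", "treatment", "block")])

  # --- trait fitting -------------------------------------------------------
  traits_fitted <- list()
  traits_table <- stage("fit", {
    rows <- list()
    keys <- split(inputs$assays,
                  interaction(inputs$assays$soil_id, inputs$assays$process,
                              drop = TRUE))
    for (d in keys) {
      assay <- thermal_assay(d$soil_id[1], d$process[1], d$temperature_c,
                             d$rate, d$replicate, low_range = config$low_range)
      tr <- fit_thermal_traits(assay, low_range = config$low_range,
                               q10_interval = config$q10_interval)
      traits_fitted[[paste(tr$soil_id, tr$process, sep = ".")]] <- tr
      rows[[length(rows) + 1L]] <- traits_as_row(tr)
    }
    do.call(rbind, rows)
  })
  log_line("fit", sprintf("%d trait sets fitted", nrow(traits_table)))

  # --- forcing and climate -------------------------------------------------
  forcings <- list()
  climate <- stage("forcing", {
    rows <- list()
    for (pid in plots$plot_id) {
      rec <- field[field$plot_id == pid, , drop = FALSE]
      fc <- build_forcing(rec, pid, config$diurnal, config$windows)
      forcings[[pid]] <- fc
      rows[[length(rows) + 1L]] <- summarize_plot_climate(fc, config$windows)
    }
    do.call(rbind, rows)
  })
  log_line("forcing", sprintf("%d plot-years of hourly forcing", length(forcings)))

  trait_list_of <- function(pid) {
    out <- lapply(processes(), function(p) traits_fitted[[paste(pid, p, sep = ".")]])
    names(out) <- processes()
    if (any(vapply(out, is.null, logical(1)))) {
      tt_stop("bad_input", sprintf("plot %s lacks fitted traits for all processes", pid))
    }
    out
  }
  refs_of <- function(pid) {
    reference_rates_from_traits(trait_list_of(pid),
                                bulk_density = config$bulk_density,
                                depth_m = config$depth_m)
  }

  # --- annual budgets ------------------------------------------------------
  budgets <- stage("budgets", {
    rows <- lapply(plots$plot_id, function(pid) {
      integrate_annual_budget(forcings[[pid]], trait_list_of(pid),
                              refs_of(pid), config$moisture, config$windows,
                              scenario = "own")
    })
    do.call(rbind, rows)
  })

  # --- scenario decomposition ---------------------------------------------
  scenarios <- stage("scenarios", {
    pairs <- pair_with_control(plots)
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      sc <- scenario_decompose(forcings[[pairs$control[i]]],
                               forcings[[pairs$treatment_plot[i]]],
                               trait_list_of(pairs$control[i]),
                               trait_list_of(pairs$treatment_plot[i]),
                               refs_of(pairs$control[i]),
                               config$moisture, config$windows)
      sc$land_use <- pairs$land_use[i]
      sc$treatment <- pairs$treatment[i]
      sc$block <- pairs$block[i]
      rows[[length(rows) + 1L]] <- sc
    }
    do.call(rbind, rows)
  })

  # --- trait ~ climate regressions ----------------------------------------
  regressions <- stage("regress", {
    rows <- list()
    for (p in processes()) for (trait in c("t_min", "t_crit", "t_max", "q10")) {
      for (pred in c("soil_mat_c", "soil_maxt_c")) {
        rows[[length(rows) + 1L]] <- tryCatch(
          trait_climate_regression(traits_table, climate, trait, p, pred),
          thermotraits_error = function(e) NULL)
      }
    }
    do.call(rbind, rows)
  })

  # --- outputs -------------------------------------------------------------
  wr <- function(df, name) {
    utils::write.csv(df, file.path(config$output_dir, name), row.names = FALSE)
  }
  wr(traits_table, "traits.csv")
  wr(climate, "climate.csv")
  wr(budgets, "budgets.csv")
  wr(scenarios, "scenarios.csv")
  wr(regressions, "regressions.csv")
  manifest <- list(
    package = "thermotraits",
    version = as.character(utils::packageVersion("thermotraits")),
    seed = config$seed, synthetic = config$synthetic,
    n_plots = nrow(plots),
    bulk_density = config$bulk_density, depth_m = config$depth_m,
    low_range = config$low_range, q10_interval = config$q10_interval)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done", "pipeline complete")
  invisible(list(traits = traits_table, climate = climate, budgets = budgets,
                 scenarios = scenarios, regressions = regressions,
                 output_dir = config$output_dir))
}
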