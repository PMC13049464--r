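# thermotraits

Soil microbial communities set the tempo of the terrestrial carbon cycle:
their growth builds biomass, their respiration returns CO₂ to the
atmosphere, and the split between the two — carbon use efficiency,
CUE = growth / (growth + respiration) — decides how much of the carbon
they consume stays in the soil. Communities also *adapt* their temperature
relationships to the climate they live in. `thermotraits` is an R package
for ecophysiologists who quantify that adaptation and ask what it means
for annual carbon budgets under warming and drought manipulations.

The package implements the full analysis chain:

1. **Thermal trait fitting.** Community temperature response curves are
   fitted to laboratory temperature-screening assays (0–45 °C in 5 °C
   steps, technical duplicates) with the dual-kinetics Ratkowsky model on
   the √rate scale:

   √G(T) = a (T − T_min)(1 − e^{b (T − T_max)})  (bacterial/fungal growth)

   √R(T) = a (T − T_min)(1 + e^{b (T − T_max)})  (respiration)

   Calibration is two-stage: ordinary least squares of √rate on T over
   0–25 °C gives the slope *a* and T_min; bounded nonlinear least squares
   over the full range then estimates *b* and T_max. The optimum T_opt
   (growth) / tipping point T_tp (respiration) is the root of
   e^{b(T−T_max)}(1 + b(T−T_min)) = 1, and
   Q10 = ((20 − T_min)/(10 − T_min))².
2. **Field forcing.** Sparse afternoon soil temperature measurements are
   inverted through a symmetric diurnal sinusoid (range linear in the
   daily mean) to daily means, gap-filled, and expanded to hourly series;
   moisture limitation uses the DAYCENT-type modifier ω(s) with the
   fine-texture constants (optimum at 60 % pore-volume saturation).
3. **Annual budgets.** Hourly rates ref·τ(T)·ω(W) are integrated to
   cumulative growth, respiration (g C m⁻² y⁻¹, top 10 cm) and CUE.
4. **Counterfactual decomposition.** Five scenarios per treated plot
   (control, treatment, temperature-only, moisture-only, adaptation-only)
   separate the direct climate effects of a manipulation from the
   indirect effect of shifted thermal traits.
5. **Synthetic data.** A generator emulating both assay and field inputs
   for a subtropical cropland/forest warming–drought experiment, so every
   stage is testable end to end without external data.

## Worked example

```r
library(thermotraits)

# ground truth from the generator, a noisy screening assay, and the fit
cfg    <- synthetic_config(land_use = "crop")
truth  <- sample_true_traits(cfg, "bacterial_growth", seed = 42)
assay  <- simulate_assay(truth, n_replicates = 2, noise_cv = 0.05, seed = 42)
traits <- fit_thermal_traits(assay)
traits
#> Thermal traits [crop_control / bacterial_growth]
#>   a = 0.01937  b = 0.1762  Tmin = -4.53  Tmax = 48.33
#>   Topt = 36.39  Q10 = 2.850  R2 = 0.9831
truth$t_min
#> [1] -4.23
```

The fitted minimum temperature (−4.53 °C) recovers the generating value
(−4.23 °C) to a few tenths of a degree at 5 % assay noise; the optimum
(36.4 °C) and maximum (48.3 °C) sit where cropland communities are
expected to, and R² = 0.98 is on the √rate scale.

```r
# a plot-year of field records, hourly forcing, and the climate summary
fy <- simulate_field_year(cfg, "crop_control_1", seed = 42)
fc <- build_forcing(fy, "crop_control_1")
summarize_plot_climate(fc)[, c("soil_mat_c", "soil_maxt_c")]
#>   soil_mat_c soil_maxt_c
#> 1         26       50.63
```

A modeled mean annual soil temperature of 26 °C with hourly peaks above
50 °C is the signature of this system: the hottest soils occur in the dry
season, when moisture (ω ≈ 0.01 at 6 % saturation) keeps realised rates
low. `integrate_annual_budget()` turns the forcing plus three fitted
curves into the annual budget, and `scenario_decompose()` splits a
treatment–control contrast into its drivers. `run_pipeline(run_config())`
executes the whole chain for a full 18-plot synthetic study and writes
traits, climate summaries, budgets, scenario tables, trait-vs-MAT
regressions, a manifest and a log.

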