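---
title: "Microbial thermal traits and annual soil carbon budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial thermal traits and annual soil carbon budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotraits)
```

## The problem

Soil microbial communities drive the largest carbon fluxes on land: growth
builds biomass (and eventually stabilised soil carbon), respiration returns
CO~2~ to the atmosphere, and their ratio — carbon use efficiency,
CUE = growth / (growth + respiration) — summarises how the carbon a
community consumes is partitioned. All three processes respond steeply to
temperature and moisture, and communities *adapt*: their temperature
response curves shift warm when their environment warms. `thermotraits`
implements the full chain needed to study this: fitting community thermal
performance curves from laboratory temperature-screening assays, deriving
trait indices, reconstructing hourly field forcing from sparse
measurements, integrating annual per-area carbon budgets, and decomposing a
climate-manipulation effect into direct temperature, direct moisture, and
trait-adaptation components.

## The dual-kinetics Ratkowsky model

The classic Ratkowsky observation is that the square root of a microbial
process rate grows linearly with temperature above a minimum temperature
$T_{min}$. The dual-kinetics (DK) extension multiplies the line by an
exponential deviation term anchored at a high temperature $T_{max}$:

$$\sqrt{G}(T) = a\,(T - T_{min})\,\bigl(1 - e^{b (T - T_{max})}\bigr)
\qquad\text{(growth)}$$
$$\sqrt{R}(T) = a\,(T - T_{min})\,\bigl(1 + e^{b (T - T_{max})}\bigr)
\qquad\text{(respiration)}$$

For growth the deviation term produces a unimodal curve with an optimum
$T_{opt}$ and a high x-axis intercept at $T_{max}$; for respiration the
sign flip makes the curve monotone, *accelerating* around a tipping point
$T_{tp}$. On the rate scale the model value is the square of the
expression, clamped at zero wherever the square-root expression is
negative (below $T_{min}$, or above $T_{max}$ for growth), so downstream
integration can never see a negative rate.

### Two-stage calibration

Screening assays expose soil subsamples to 0–45 °C in 5 °C steps
(technical duplicates). Fitting follows the two-stage scheme the assay
design implies:

1. **Low range (0–25 °C).** There the exponential term is small and the
   model reduces to the plain Ratkowsky line. An ordinary least-squares
   fit of $\sqrt{rate}$ on $T$ gives $a$ (slope) and
   $T_{min} = -\text{intercept}/a$. Technical duplicates enter as
   independent observations — averaging first would discard degrees of
   freedom and the duplicate-level noise structure.
2. **Full range.** With $a$ and $T_{min}$ frozen, $b$ and $T_{max}$ are
   estimated by bounded nonlinear least squares on the $\sqrt{rate}$ scale
   over all ten temperatures (Gauss–Newton with box constraints, four
   starting points, quasi-Newton polish). $R^2$ is reported on the
   $\sqrt{rate}$ scale, matching the scale on which the model is stated.

Bounds are $b \in (10^{-3}, 2]$ and
$T_{max} \in (\max T_{obs} - 5, 80]$ °C. If the assay carries no
information on the high-temperature response (the pure square-root line
fits as well as the DK optimum), $T_{max}$ is reported at its upper search
bound with an explicit `tmax_bound_hit` diagnostic rather than an
arbitrary plateau value.

### Derived indices

The critical temperature is the root of the derivative condition

$$e^{b (T - T_{max})}\,\bigl(1 + b\,(T - T_{min})\bigr) = 1$$

in $(T_{min}, T_{max})$, located by bracketed root search to $10^{-8}$ °C.
For growth this is $T_{opt}$, the curve's maximum. The respiration curve
itself is monotone — its own derivative has no real root for $b > 0$ — so
the package applies the same growth-form condition to the fitted
respiration parameters and reports the result as $T_{tp}$. This is a
deliberate, overridable policy: it places $T_{tp}$ where the curve departs
from square-root behaviour, inside the observed temperature range,
consistent with reported tipping points in the low-to-mid 30s °C.
`thermal_traits()` accepts an explicit `t_crit` for users who prefer a
different convention.

Temperature sensitivity uses the square-root model's closed form over the
conventional 10–20 °C interval:
$Q_{10} = \bigl((20 - T_{min})/(10 - T_{min})\bigr)^2$, which equals the
model's rate ratio wherever the exponential term is negligible.

## From sparse field records to hourly forcing

Field soil temperature is measured twice a week in the early afternoon
(14:00–16:00, near the diurnal maximum), at 5 cm depth. The package
reconstructs hourly forcing with a symmetric sinusoid around the daily
mean whose range is a linear function of that mean:

$$T(h) = \bar{T} + \tfrac{\max(0,\ \alpha + \beta \bar{T})}{2}
 \sin\!\Bigl(\tfrac{2\pi (h - h_{peak})}{24} + \tfrac{\pi}{2}\Bigr)$$

Each afternoon observation is *inverted* through this sinusoid at the
measurement hour to recover the daily mean (monotone one-dimensional root
solve); days between measurements are filled by linear interpolation of
the daily means. The defaults $\alpha = 8$ °C, $\beta = 0.2$ and
$h_{peak} = 14$ are configuration values: the range–mean relation of a
real site would be calibrated against local high-resolution climate data,
which is outside this package's scope, so the synthetic generator shares
the same parameters and the inversion is exactly testable (expanding a
recovered mean reproduces the measurement to $10^{-6}$ °C). Moisture
varies much more slowly than temperature, so it is linearly interpolated
between measurement days at daily resolution and held constant within a
day.

Moisture limitation uses the DAYCENT-type dimensionless modifier

$$\omega(s) = \Bigl(\tfrac{s - c_2}{c_1 - c_2}\Bigr)^{c_4 (c_2 - c_1)/(c_1 - c_3)}
 \Bigl(\tfrac{s - c_3}{c_1 - c_3}\Bigr)^{c_4}$$

with the fine-texture calibration $c_1 = 0.6$, $c_2 = 1.27$,
$c_3 = 0.0012$, $c_4 = 2.84$: $\omega = 1$ at relative saturation
$s = 0.6$, zero at $s \le c_3$, clamped to $[0, 1]$. Field moisture is
recorded as percent of pore-volume saturation, so $s = W/100$ by default;
because published forms of this function are sometimes written in terms of
volumetric water content, `moisture_params(input = "volumetric")` applies
$s = W/(100\,\phi)$ with porosity $\phi$ instead. Both pathways are
provided because the two conventions differ materially in dry soils;
saturation is the default as it matches the field instrument's output.

The season calendar (dry: 8 Feb–26 May 2018 and 21 Jan–10 Feb 2019; wet:
27 May 2018–20 Jan 2019; endpoints inclusive) partitions the 368-day
modeled year, and the constructor rejects windows that overlap or leave
gaps.

## Annual budgets and counterfactual scenarios

Each hourly process rate is a reference rate modulated by the two
normalized response functions:

$$\text{rate}_p(h) = \text{ref}_p \cdot \tau_p(T_h) \cdot \omega(W_h),
\qquad \tau_p(T) = \frac{\text{rate}_p(T)}{\text{rate}_p(T_{crit})}$$

Growth $\tau \in [0, 1]$; respiration $\tau$ exceeds 1 above $T_{tp}$
because the curve keeps rising. One shared moisture function serves all
three processes (per-process overrides are accepted), since only a single
moisture calibration is available. Reference rates default to the fitted
curve evaluated at its own critical temperature; they can alternatively be
anchored to a rate measured at a common lab temperature, scaled along the
fitted curve (`reference_rates_from_traits(measured = ...)`), or set
directly.

Cumulative totals use a left-endpoint Riemann sum at the forcing's 1-hour
step, converted to g C m⁻² for the top 10 cm of soil via
`bulk_density × depth` (default 1.1 g cm⁻³ × 0.10 m; bulk density is a
configuration value because it is site-specific). Integration is exactly
additive over partitions of the year, and doubling all reference rates
doubles both totals while leaving CUE unchanged — both properties are
asserted in the test suite.

`scenario_decompose()` builds the five budgets that separate a treatment
effect: control, treatment, and the three virtual scenarios that swap one
driver at a time against the control baseline (treatment temperature
series, treatment moisture series, or treatment traits), with reference
rates held at control values. Null treatments collapse all five to
identical budgets, and a traits-only difference makes the adaptation
scenario equal the full treatment — identities the acceptance tests check
to $10^{-12}$.

## The synthetic-data generator

The generator emulates the two input kinds of a warming/drought field
experiment on a subtropical cropland–forest pair, so the entire pipeline
is testable without any external data.

* **Field years.** Twice-weekly afternoon records over the modeled year,
  drawn per season around the study conditions: cropland
  41.8 ± 5.2 °C (dry) and 26.7 ± 5.1 °C (wet) with moisture
  6.1 ± 4.3 % and 30.5 ± 12.7 %; forest 29.8 ± 3.7 / 21.9 ± 3.4 °C and
  10.5 ± 3.8 / 37.2 ± 14.0 %. Open-top chambers add +3.9 °C to the
  cropland dry season (+0.9 °C in the shaded forest); rain shelters lower
  forest wet-season moisture to a 30.4 % mean and cool the cropland dry
  season by 1.2 °C. A lag-1 autocorrelation of 0.5 within each season
  makes the interpolation machinery work on realistically smooth series;
  set `ar_rho = 0` for white noise.
* **Traits and assays.** Critical temperatures and $T_{max}$ are drawn
  uniformly within the reported ranges ($T_{opt}$ 33–38 °C bacteria,
  36–40 °C fungi, $T_{tp}$ 32–40 °C; $T_{max}$ 47–49 / 47–50 °C for
  growth). No respiration $T_{max}$ range is reported, so 46–54 °C was
  chosen once as a realistic span consistent with acceleration in the
  mid-30s. Given a draw, the shape parameter $b$ is *solved* from the
  derivative condition (`solve_b_for_tcrit()`), so every generated curve
  is internally consistent, and the slope $a$ is set so the rate at the
  critical temperature matches a configured magnitude (0.5, 0.35 and
  2.5 µg C g⁻¹ h⁻¹ for bacterial growth, fungal growth and respiration —
  proportions that put the system's CUE near the 0.2–0.3 observed for
  such soils). Assay noise is multiplicative Gaussian on the
  $\sqrt{rate}$ scale (CV 5 %), where the stage-1 OLS assumptions hold.
* **Adaptation coupling.** When a plot's modeled mean annual soil
  temperature (MAT) is supplied, growth $T_{min}$ is drawn around a line
  with slope 0.25 °C per °C MAT (SD 0.3 °C), respiration with a weak
  opposite slope, and the positions of $T_{crit}$ and $T_{max}$ inside
  their prior ranges shift warm with MAT. `simulate_study()` wires this
  together for the full 2 × 3 × 3 design.

### What the generator does and does not emulate

It reproduces the seasonal climate statistics, treatment offsets, assay
design and noise scale, and a climate–trait coupling of realistic
magnitude. It does **not** emulate within-season weather structure beyond
AR(1), measurement error in the field sensors, block-level spatial
correlation, or community dynamics: passing tests demonstrate the
*machinery* is correct under the stated statistical structure, not that
real soils behave this way.

## Numerical choices and degenerate inputs

* Stage-1 requires ≥ 3 distinct low-range temperatures; assays with fewer
  (or < 5 overall) are rejected at construction.
* Negative measured rates (instrument noise near zero) are truncated to 0
  at ingestion, with a message carrying the count.
* Root searches (critical temperature, diurnal inversion) use bracketed
  `uniroot` at tolerances 1e-8 °C and 1e-10; the diurnal inversion
  verifies monotonicity of the inversion equation first.
* Interval endpoints of season windows and the low fitting range are
  inclusive; dates are ISO-8601 in files.
* Budget integration refuses forcings with missing hours unless the
  coverage check is explicitly disabled for toy series.

## Known limitations

* **Two-stage identification bias.** When the reported
  $T_{opt}/T_{tp}$ and $T_{max}$ ranges are pushed through the derivative
  condition they imply shape parameters around $b \approx 0.15$, at which
  the exponential term contributes a few percent to $\sqrt{rate}$ already
  at 20–25 °C. Stage-1 OLS absorbs that contribution into the slope, so
  even on noiseless data the recovered $T_{min}$ is biased (up to
  ~0.5 °C for respiration, smaller for growth). This is a property of the
  two-stage calibration itself, visible in the package's own recovery
  experiment; it disappears for sharper curves ($b \gtrsim 0.25$).
* **Extrapolation above the screening range.** Dry-season soil
  temperatures exceed 45 °C, beyond the assay grid. The monotone
  respiration curve's exponential term then amplifies the hottest hours
  strongly ($\tau \gg 1$), which can make the *direct* temperature effect
  of warming on respiration positive in the synthetic world even though
  the adaptation effect is negative — the decomposition keeps the two
  visible separately, which is precisely its purpose.
* Heat transport with depth damping is not modeled; the surface sinusoid
  is applied directly to the 5 cm measurement depth.
* No uncertainty intervals on fitted traits; the duplicate-level fit is a
  point estimate.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the full pipeline on the
synthetic 2 × 3 × 3 design (18 plots, 54 assays, 8 832 hourly steps per
plot-year), a 100-assay parameter-recovery experiment, and 200-seed pooled
checks of the field generator's seasonal statistics — sizes chosen so the
whole suite completes in well under a minute on one core while keeping
Monte-Carlo error far below the asserted tolerances.
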