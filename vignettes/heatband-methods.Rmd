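---
title: "Methods: from daily climate ensembles to heat-health indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from daily climate ensembles to heat-health indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatband)
```

## The problem

Sustained high apparent temperatures are a direct risk to human health:
heat stress grows with air temperature and humidity and is relieved by
wind. Regional climate-model ensembles project daily maximum temperature,
relative humidity and wind decades ahead, but raw model output carries
systematic biases, and health stakeholders need the output translated into
interpretable indicators — how many days per year exceed temperatures at
which heat begins to affect health, how fast that number is rising, and
whether the rise is statistically significant.

`heatband` implements that translation as a five-stage pipeline:

1. **Bias correction** of daily maximum temperature (additive) and relative
   humidity (multiplicative) against a reference monthly climatology.
2. **Apparent temperature**: the non-radiative Australian Bureau of
   Meteorology index applied daily.
3. **Heat-day counting** against fixed apparent-temperature thresholds and
   symptom bands.
4. **Trend characterisation**: 11-year moving averages, ensemble
   percentile envelopes, average rates of increase, and a Monte Carlo
   re-randomization significance test.
5. A **synthetic-climate generator** that emulates the statistical surface
   of a downscaled ensemble with known ground truth, so every stage above
   is testable without external data.

## Calendar and grid conventions

All daily data use a **365-day (no-leap) calendar**, the common archival
calendar for climate-model output. This keeps every year at exactly 365
classified days, so the conservation identity `Hda1 + Hda2 = 365` is exact.
Grids are regular latitude–longitude, latitudes ascending south to north,
longitudes in [−180, 180). Years are counted inclusively on both ends
everywhere ("1961–1990" has 30 years).

## Bias correction

Model and reference are compared as **monthly climatologies over a
baseline window** (default 1961–1990): for each calendar month and cell,
the mean of all daily values in that month across the baseline years.
Temperature receives an additive correction (reference − model, per month
and cell); relative humidity a multiplicative factor (reference ÷ model,
missing where the model climatology is zero). The correction is applied to
**every year of the record**, not only the baseline, and corrected
humidity is clipped to [0, 100] % with the clipped fraction reported as a
QC metric.

Design choices made here, where more than one reading was defensible:

* Corrections are **per calendar month** — twelve values per cell and
  variable — with no smoothing across month boundaries. Step changes at
  month edges are accepted; they are the price of a correction whose
  baseline-matching property is exactly testable (the corrected baseline
  climatology equals the reference to floating-point accuracy, which the
  test suite asserts at 1e-9).
* When model output is on a different grid than the reference, the daily
  fields are **bilinearly regridded first, then corrected**, so that
  corrections are derived and applied on one grid.
* **Wind is not bias-corrected**: the correction scheme is defined for
  temperature and humidity only, and wind enters the apparent-temperature
  index with a small coefficient.
* Additive correction preserves day ordering within a month and
  year-to-year differences of monthly means (trends); multiplicative
  correction preserves ordering wherever the factor is positive. Both
  properties are tested.

## Apparent temperature

The index is

$$AT = T_a + 0.33\,e - 0.70\,ws - 4.00$$

with $T_a$ dry-bulb temperature (°C), $e$ water vapour pressure (hPa) and
$ws$ 10 m wind speed (m/s). Vapour pressure comes from relative humidity
through the Magnus saturation curve
$e_s(T) = 6.105 \exp\!\big(17.27\,T/(237.7+T)\big)$, $e = (rh/100)\,e_s$.
The Magnus constants are defined once, in one place.

The daily maximum AT is formed from the **same day's** tmax, RH and wind,
with $e$ evaluated at tmax. Source archives rarely state whether daily RH
is a daily mean or the value coincident with the temperature maximum; the
package adopts the tmax-coincident convention, which maximises AT for
given daily fields, and documents it as a convention rather than a fact
about any particular archive. Negative AT values are retained — they can
only ever land in the lowest category.

## Heat days and symptom bands

Daily maximum AT is classified against the US National Weather Service
symptom chart: nested hot-day categories
`Hda2..Hda5` (AT ≥ 27, 32, 39, 51 °C) with `Hda1` the complement
(AT < 27 °C), and four disjoint symptom bands partitioning [27, ∞):
I Caution [27, 32), II Extreme Caution [32, 39), III Danger [39, 51),
IV Extreme Danger [51, ∞). The printed band ranges touch at 32, 39 and 51;
the package resolves the boundary by the category inequalities — **all
thresholds are inclusive on the left**, so AT = 32.0 is Hda2 ∧ Hda3 and
Band II.

Counts are per **calendar year** (January–December). Conservation
(`Hda1 + Hda2 = 365`, `ΣBands = Hda2`) and nesting
(`Hda2 ≥ Hda3 ≥ Hda4 ≥ Hda5`) are asserted on every call, not only in
tests. A cell-year with any missing day is excluded (set missing with a
warning) rather than rescaled. Time-slice summaries average annual counts
over 30-year windows (1961–1990 baseline; 2011–2040, 2041–2070, 2071–2100
futures); ensemble averaging happens **after** the per-member time-slice
mean (mean of member means), and change maps are future − baseline per
cell.

## Trends

Annual count series are smoothed with a **centered, unweighted 11-year
moving average**; a 1961–2100 series yields valid centres 1966–2095. The
ensemble is summarised per year by the 10th percentile, median and 90th
percentile across members, with linear interpolation between order
statistics (type 7) — fixed explicitly because with six members the outer
percentiles are interpolation-sensitive, and the six-member median is then
the mean of the 3rd and 4th order statistics.

The **average rate of increase** is the smoothed change between the last
and first valid centres divided by the span. Two denominator conventions
are exposed because both appear in practice: `"inclusive"` counts both end
years (1966..2095 → 130 years) and is the default, matching the convention
under which such rates are conventionally printed; `"difference"` uses the
year difference (129) and recovers the generating slope of a linear series
exactly. The choice changes rates by less than 1 %.

**Significance** uses a Monte Carlo re-randomization test: the observed
statistic is the OLS slope of the (smoothed) series on its year axis; the
null distribution is built by resampling the observed values **with
replacement** (destroying temporal order) 1000 times and recomputing the
slope of each resample. The trend is significant at level L% if the
observed slope strictly exceeds at least L% of the null slopes. Choices
made where the procedure was underdetermined:

* The trend statistic is the OLS slope — transparent and admitting
  closed-form oracles.
* Resampling is an iid value bootstrap, the literal reading of
  "resampling with replacement". On an 11-year-smoothed series this null
  is anti-conservative (smoothing induces autocorrelation the resampling
  destroys); the package keeps the literal method as the default and the
  test-calibration checks are therefore run on *unsmoothed* iid series,
  where the test holds its nominal size (rejection at the 95 % level on
  500 iid Gaussian series falls in [0.03, 0.07]).
* Ranking is one-sided (increasing) by default — warming projections ask
  the increasing question — with a two-sided option.
* Ties between the observed and null slopes count **against**
  significance (conservative).
* Cells whose raw series is structurally constant at 0 or 365 days/year
  cannot exhibit a trend and are flagged `-1` ("no trend possible")
  rather than "not significant": a region already at the ceiling is a
  different scientific statement than a region with no detectable trend.
* No multiple-testing correction is applied across grid cells; per-cell
  significance maps should be read accordingly. This is a documented
  limitation.

## The synthetic generator

`synthConfig()` / `generateEnsemble()` emulate the statistical surface a
downscaled regional ensemble presents to this pipeline — not the dynamics
of any climate model. Per member, daily tmax is

baseline(lat) + seasonal cycle + trend·(elapsed years)/100
+ monthly additive bias + noise,

with a hemisphere-aware seasonal phase (southern-hemisphere cells peak in
mid-January, northern in mid-July), and RH is (baseline + trend + noise) ×
monthly multiplicative bias, clipped to [0, 100]. Wind is mean + noise,
floored at zero, with no bias and no trend. Defaults describe the target
study conditions: **six members, 1961–2100**, a 3 °C/century warming
trend, 6 °C seasonal amplitude, ±1.5 °C monthly temperature bias,
0.9–1.1 humidity bias factors, 1 °C / 5-point daily noise, on a coarse
(2°) southern-African-style grid — coarse because the pipeline's
properties, not the spatial detail, are under test. The warming trend
steps **annually** (elapsed = year − first year), which makes two
identical calendar days a century apart differ by exactly the trend and
makes smoothed-rate recovery a closed form. Daily noise is independent
across days and cells by default; an AR(1) coefficient is available for
power studies.

`generateReferenceClimatology()` returns the bias-free monthly
climatology implied by the same configuration — the truth the bias
correction should restore — so correction exactness is testable to
floating point, and noisy-generation checks have analytic standard
errors.

What the generator deliberately does **not** emulate: topography,
spatially correlated weather systems, humidity–temperature coupling,
seasonal humidity cycles, non-Gaussian daily extremes, and non-linear
warming paths. Passing tests therefore demonstrate the pipeline's
algorithmic correctness and calibration, not the realism of any climate
projection.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes that still exercise every code path meaningfully: bias
correction exactness on a 10 × 10 grid × 30 years; counting equivalence
against a scalar-loop oracle on 100 random cell-years; Monte Carlo size
on 500 iid series of length 130 (the smoothed-series length) at 1000
resamples; trend recovery on a 5 × 5 grid with a known 0–4 °C/century
warming field over 1961–2100; and a full six-member 1961–2100 pipeline on
a 4 × 4 grid. Degenerate inputs are handled explicitly: constant series
yield slope 0 and no significance without resampling; series shorter than
the window, disjoint grids, misaligned axes and uncovered baselines are
errors naming the offending years or grids; nearest-cell extraction
breaks exact ties toward the lower (southern/western) index.

## Reproducibility

Every stochastic component is seeded: the generator's seed lives in its
configuration, the Monte Carlo seed in the test call or pipeline
configuration, and `runPipeline()` writes a manifest with a configuration
hash, both seeds, the package version and per-stage output checksums.
Two runs with identical configuration are byte-identical, which the test
suite asserts.
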