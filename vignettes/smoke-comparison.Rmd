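---
title: "Methods: comparing wildfire and prescribed-burn smoke scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing wildfire and prescribed-burn smoke scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxsmoke)
```

## The scenario question

`rxsmoke` compares three emission scenarios over an identical set of fires
and an identical total burned area:

* **wildfire** — fires burn on the days and in the cells where they were
  detected;
* **Rx1** — each fire's area is re-assigned to a spring (Mar–May) or fall
  (Sep–Nov) day whose meteorology in the fire's cell satisfies a
  prescribed-burn window;
* **Rx2** — as Rx1, but days forecast to produce high population-weighted
  exposure are embargoed before the meteorological filters are applied.

Because location and area are held fixed, every downstream difference —
emissions, concentrations, exposure, mortality — is attributable to *when*
and *under what conditions* the fuel burns. This is a scenario comparison,
not a forecast: it deliberately ignores whether prescribed burns of
wildfire-scale extent are operationally achievable.

## Emissions model

Emitted mass of species $s$ for one fire-day is

$$E_s = \sum_{FT} \mathrm{BA} \cdot FC_{FT} \cdot EF_{s,FT}$$

with burned area BA (km²), fuel consumed $FC$ (kg/km²) per fuel type and
emission factors $EF$ (g/kg). The shipped factor table
(`inst/extdata/emission_factors_pm25.csv`) carries the six PM2.5 entries:
western forest 17.57 (Rx) / 23.2 (wildfire) g/kg for short-term flaming and
smoldering (STFS), shrubland 7.06, grassland 8.51, and residual smoldering
combustion (RSC) factors of 33 (woody) and 35.3 (duff) g/kg. Other species
(e.g. CO, CO₂) can be supplied through the same schema; none are hard-coded.

**Cover-type classification.** A cell's fuel bed is forest if canopy+woody
is the largest of the shares {canopy+woody, shrub, nonwoody}, shrubland if
shrub is largest, grassland if nonwoody is largest. Duff is excluded from
the comparison; ties break forest > shrubland > grassland (an arbitrary but
fixed precedence); an all-zero bed is an error rather than a silent default.

**Consumption.** Full fuel-consumption models resolve many fuel classes and
moisture regimes; `rxsmoke` replaces that machinery with a parameterized
scheme that keeps the two levers the scenario contrast depends on:

| parameter | default | meaning |
|---|---|---|
| canopy consumed fraction | 0.5 wildfire / 0.0 Rx | crown involvement is the key wildfire/Rx difference |
| shrub blackened fraction | 0.5 (both types) | standard operational assumption |
| surface consumed fraction | 0.9 at fuel moisture 0 → 0.3 at 1, linear | consumption decreases with moisture |
| RSC share of consumed woody / duff | 0.3 / 1.0 | smoldering split for the RSC factors |
| fuel moisture from soil moisture | linear onto [0.05, 0.40] | monotone placeholder for an operational moisture model |

All are configurable (`consume_params()`, `fuel_moisture_from_soil()`).
Consumption never exceeds loading per category, and the STFS/RSC split sums
exactly to the category totals; both are property-tested over random beds.

## Scheduling model

The strict burn window is wind < 5.36 m/s (12 mph), temperature < 29.5 °C
(85 °F), RH ∈ [0.25, 0.45] and soil moisture ∈ [0.15, 0.3] m³/m³, evaluated
in the fire's own grid cell over all spring/fall days. Among qualifying days
the **lowest-wind** day is chosen (minimizing escape risk); equal winds
break to the earliest date — a documented, deterministic tie-break. If no
day qualifies, a fallback tier relaxes wind to < 6.7056 m/s (15 mph) and the
RH ceiling to 0.6. The fallback retains the temperature and soil-moisture
bounds and the RH floor: only the two named relaxations are applied. Both
choices are configurable in `burn_window_criteria()`. If even the fallback
tier is empty the scheduler raises an error naming the fire — silently
keeping the wildfire date would corrupt the scenario contrast.

Multi-day events whose area lies entirely within one grid cell on
consecutive days are collapsed to a single burn day (areas summed); events
spanning several cells are scheduled per-row independently, since a single
prescribed burn day is only plausible for a contiguous single-cell area.
Total burned area is conserved exactly in every mode.

**Exposure screening (Rx2).** For each spring/fall day,
`screen_high_exposure_days()` forecasts the population-weighted PM2.5 that
would result if every pending fire emitted one unit of mass in its cell on
that day (one surrogate transport step under that day's winds at the
prescribed-burn mixing depth), then embargoes days whose forecast exceeds
the 0.9 quantile of the distribution. The quantile is configurable;
`quantile_cut = 1` embargoes nothing. A fixed four-period calendar
(`no_burn_2012()`: Apr 27–May 2, May 28–Jun 2, Oct 26–28, Nov 2–5) is
shipped as a preset for users who want to prescribe the embargo directly.
Because the calendar only removes candidate days, Rx2 candidate sets are
always subsets of Rx1's.

## Dispersion surrogate

The transport kernel is intentionally the simplest operator that exhibits
transport-direction sensitivity — the mechanism by which a scenario with
*lower* emissions can produce *higher* exposure:

1. yesterday's airborne mass decays by $e^{-1/\tau}$ (default lifetime
   $\tau$ = 1.5 days);
2. today's emissions are added;
3. each cell's mass is displaced along its own wind vector
   (`advection_scale` × wind × 86.4 km/day; default scale 0.2, representing
   the effective daily displacement of the surface-relevant plume) and
   deposited bilinearly — mass crossing the domain edge is lost (open
   boundaries);
4. the field is spread by a separable Gaussian (default 15 km/day); the
   discrete kernel is normalized in the interior, so edge leakage is the
   only mass sink besides decay;
5. surface concentration is mass diluted through cell area × mixing depth,
   with depths of 3000 m (wildfire) and 1300 m (prescribed), reflecting
   observed plume-top heights — identical emissions therefore produce
   surface concentrations 3000/1300 ≈ 2.3× higher under prescribed
   conditions.

The operator is linear in emissions, so the "with fires minus without
fires" difference that the health module needs is exact by construction (the
no-fire increment is identically zero). Closed forms — single-cell box
dilution of 1 g into (12 km)² × 1000 m, and the mixing-depth concentration
ratio — are asserted to six significant figures in the tests. The kernel is
**not** a chemical transport model: no chemistry, no secondary aerosol, no
vertical structure, no meteorological feedback, and its concentration
magnitudes are surrogate-scale only. A 24-hour diurnal re-weighting
(`apply_diurnal_profile()`) is available but the pipeline operates daily,
matching the daily health mathematics.

## Exposure and mortality

Population-weighted exposure is $PW = \sum_i P_i C_i / \sum_i P_i$. Daily
excess mortality is

$$M = \sum_i P_i \cdot I \cdot \frac{RR_i - 1}{RR_i}, \qquad
RR_i = \exp\{\gamma\,(C^{F}_i - C^{NF}_i)\}$$

with $\gamma$ = 0.00101 per µg/m³ (95% CI 0.001001–0.001020, specific to
fire-derived PM2.5) and baseline rate $I$ = 813 deaths per 100,000 per year
divided by 365. The attributable-fraction form $(RR-1)/RR$ is the standard
choice in the short-term fire-mortality literature; the alternative $(RR-1)$
form — which does not cap the fraction at 1 — is available via
`health_params(af_form = "excess")` and yields strictly larger estimates.
Confidence bounds re-evaluate the whole chain at the $\gamma$ CI endpoints,
so their ordering is inherited from monotonicity in $\gamma$. Exposure is
weighted equally across people; no age structure or exposure-avoidance
behaviour is modeled.

## Evaluation statistics

Stations are matched to the Euclidean-nearest cell centre (ties: lower row,
then lower column). NMBF and NMAEF use the symmetric factor forms:

$$\mathrm{NMBF} = \begin{cases}\bar M/\bar O - 1 & \bar M \ge \bar O\\
1 - \bar O/\bar M & \bar M < \bar O\end{cases}\qquad
\mathrm{NMAEF} = \frac{\sum_i |M_i - O_i|}{n\,\bar O \text{ or } n\,\bar M}$$

with the same branch rule, so overprediction and underprediction by the same
factor score symmetrically and NMAEF ≥ |NMBF| always. Pearson r drops
missing pairs and is reported as missing for constant series. Station-level
statistics are averaged with equal station weights.

## The synthetic generators

The generators emulate the *structure* the pipeline's filters and kernels
need, not any reanalysis climatology:

* **Meteorology** — per-season Gaussian anomalies (a domain-wide daily term
  plus a spatially smoothed cell term, equal variance shares), truncated to
  physical ranges. Season means are chosen so that a large fraction of
  spring/fall cell-days pass the strict burn window while summer cell-days
  essentially never do (the tests assert ≥ 30% for April and < 5% for
  summer by independent filtering). Wind bearings default to southward
  (toward the populated cells) in spring/fall and northeastward in summer,
  giving the two fire seasons different transport.
* **Fires** — monthly ignition weights concentrated May–September; sizes
  lognormal with mean 1.4 km² and a heavy tail (sdlog 1.8); fires above
  10 km² span consecutive days and sometimes a neighbouring cell.
* **Population** — Gaussian clusters confined to the southern 35% of rows;
  integer rounding redistributes remainders so the configured total is
  conserved exactly.
* **Fuel beds** — cells draw a dominant type (50% forest, 30% shrubland,
  20% grassland) and lognormal loadings around type means. The forest bed
  is canopy-heavy (1.0 × 10⁶ of 2.2 × 10⁶ kg/km²), as in a crown-fire-prone
  conifer forest, so the canopy-consumption difference between fire types
  has substantial leverage.
* **Observations** — optional synthetic monitor series (modeled field +
  background + lognormal noise), labelled synthetic; they exist to exercise
  the evaluation statistics, not to represent real monitors.

Each generator seeds its own RNG stream from the master seed, so outputs
are bit-identical under a fixed seed regardless of call order. What passing
tests on these inputs shows is that the *algorithms* behave as specified
under realistic structure; it does not show that real meteorology offers as
many burn days, that real fires are placed like these, or that surrogate
concentrations match a transport model's.

## Numerical choices and degenerate inputs

* Non-leap 365-day calendar; all dates are day-of-year integers.
* Percent reductions in the scenario report round half away from zero to
  integers; a zero baseline yields an `(n/a)` bracket instead of dividing.
* Truncation (wind ≥ 0, RH and soil moisture clipped to [0, 1]) slightly
  distorts the Gaussian marginals; the burn-window margins are wide enough
  that this is immaterial.
* The screening embargo uses strict inequality against the quantile, so
  tied forecasts at the threshold are kept.
* A negative fire-minus-no-fire concentration difference is a validation
  error in `relative_risk()` — the surrogate guarantees non-negative
  increments, so a negative value indicates mismatched inputs.
* Zero total population, all-zero fuel beds, all-zero diurnal weights and
  empty month subsets are errors, not silent zeros; an empty fire list
  flows through the whole pipeline as a valid (all-zero) scenario.

## Problem sizes

The default end-to-end configuration — a 20 × 20 grid of 12 km cells, 200
fires, 365 days — runs in a few seconds on one core and is the size used by
the test suite and the acceptance script; property tests use up to 10⁴
random fuel beds and 10³ random series. The schedulers are exact
(exhaustive-search-equivalent), so small domains lose no generality.

## Known limitations

* The dispersion surrogate supports directional, qualitative comparisons
  only; absolute concentrations and mortality counts are surrogate-scale.
* Consumption is a five-category parameterization, not a fuel-bed-specific
  consumption model; the RSC split fractions are round-number defaults.
* Re-scheduling treats fires independently; no crew, permit, escape-risk or
  multi-year planning constraints.
* Gridded I/O is long-format CSV (`write_field_csv()`); fields are small at
  these problem sizes, and the format keeps every artifact plain text.
* The exposure screen forecasts with unit emissions, so it ranks days by
  transport geometry alone, not by the actual emission magnitude eventually
  scheduled onto them.
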