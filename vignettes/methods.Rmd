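---
title: "Methods: Monte Carlo estimation of seabed carbon disturbance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo estimation of seabed carbon disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dredgecarbon)
```

## The model

The quantity estimated is *carbon disturbance*: the mass of sedimentary
organic carbon contained in sediment that is mechanically removed by port
dredging or marine aggregate extraction. It is not the (smaller) mass
remineralised to CO~2~ — modelling the biogeochemical fate of disturbed
sediment is out of scope. The accounting identity per event is

$$
\mathrm{kgC} = \mathrm{kg\ sediment} \times \frac{\%\mathrm{TOC}}{100},
$$

with two stochastic ingredients:

* **%TOC** is unknown at the event's exact footprint, so it is drawn from
  an empirical distribution of measured values pooled over the relevant
  context — samples within 5 km of the coast (below mean high water,
  excluding seagrass and saltmarsh habitats) for port dredging; samples
  overlapping sand, coarse, or mixed sediment-class polygons for aggregate
  extraction, with a combined pool for records whose sediment type is
  unreported.
* **Mass** is known for most events (after unit harmonisation) but missing
  entirely from many 19th-century UK port returns. Missing masses are drawn
  inside the simulation from a normal model on log10 kg fitted to the
  events with known masses, back-transformed as $10^x$ so every draw is
  positive.

A Monte Carlo simulation (default 10,000 runs) redraws both ingredients in
every run, accumulates carbon per (industry, scope, year), and summarises
each cell's run totals by their mean, n−1 standard deviation, and 5th/95th
percentiles.

### Why empirical resampling rather than a fitted distribution

The %TOC pools are used as-is: draws resample observed values uniformly
with replacement. No kernel smoothing or parametric family is imposed, so
draws can never leave the observed range, pool percentiles are reproduced
without distributional assumptions, and a pool with heavy right skew (the
coastal pools are strongly right-skewed, with medians far below means)
contributes exactly its observed skewness to the output bands.

### Harmonisation and unit conventions

All quantities are converted to kilograms on ingestion. Pre-20th-century UK
sources report long tons (1016 kg); the modern tonne (1000 kg) is a
distinct unit value, and sources must declare which they use. Volumes (m³,
cubic yards via 0.764554858 m³/yd³) are converted with a single average
marine-sediment density of 1700 kg/m³, configurable but deliberately shared
across all records because source documents rarely state sediment type or
dry bulk density. Costs are converted with an average cost-per-kg rate
calibrated on records that report both cost and quantity; the default rate
is the unweighted mean of per-pair ratios, with total-cost/total-mass
available as a configuration switch (it weights pairs by mass, which lets a
single large dredging campaign dominate the rate — hence not the default).

Multi-year period returns are split equally across their years as real
numbers, with the last year absorbing the floating-point remainder so the
per-year masses sum back to the reported total exactly. Period records with
*no* quantity produce a single period-level imputation event — masses are
imputed per dredging works, not per year — whose drawn mass is spread
equally over the period's years inside the simulation.

Years in which fewer than two countries contributed records are dropped
before shelf-wide analysis (`exclude_sparse_years()`, threshold
configurable): a single-nation year would be a large underestimate at shelf
scale. Records of maerl extraction and of historical non-aggregate
commodities (tin prospecting, clay, shingle, trial boreholes) are excluded
with per-record audit reasons, because they lack organic-carbon
characterisation or usable masses.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_runs` | 10,000 | runs | the convergence study's inter-iteration spread is well below 1% of the mean at this count |
| `percentiles` | 5, 95 | % | conventional reporting bounds for this kind of first-order estimate |
| `density_kg_m3` | 1700 | kg/m³ | average marine-sediment wet bulk density used for all volume conversions |
| `max_dist_km` | 5 | km | coastal/inshore definition for the dredging %TOC pool; boundary samples are retained (closed interval) |
| `draw_scope` | `per_record` | — | one %TOC draw per event per run; see below |
| `min_countries` | 2 | countries | sparse-year exclusion threshold |
| `redraw_imputed` | TRUE | — | imputed masses are redrawn every run; a fix-once mode is available |

### Draw scope

Whether "a %TOC value is randomly selected each run" means one draw per
*event* or one per *year total* is a genuine modelling choice. The default
(`per_record`) draws per event, which averages %TOC variability across the
many events in a year and yields narrower bands; `per_year_total` applies a
single draw to each (scope-year, distribution) cell's total mass and yields
wider bands (for $k$ equal events the run-total SD is larger by about
$\sqrt{k}$). Both are implemented; the tests assert the same expectation
and the widening. Users comparing against analyses that draw per year
should switch explicitly.

### Seeding

One master seed spawns deterministic substreams per (industry, scope)
group, via a small string hash folded with the seed (kept below 2³¹, the R
seed range). Consequences, both tested: a country's results are bit-for-bit
reproducible whether it is simulated alone or jointly with others, and
shelf (or national) results are computed by summing the retained per-run
totals across countries (or ports), so aggregation conservation is exact by
construction rather than approximate.

## Numerical choices

* Percentiles use linear interpolation between order statistics
  (`quantile()` type 7, the default of mainstream statistical
  environments); the choice is recorded in the result's metadata.
* SDs use the n−1 denominator throughout (over Monte Carlo run totals and
  over annual means).
* The log10-mass fit reports a Shapiro–Wilk W and p on the log10 values as
  a descriptive diagnostic; it does not gate imputation. The statistic is
  computed for 3 ≤ n ≤ 5000 (its defined range) and reported as NA
  otherwise. Degenerate fits (σ = 0) refuse to impute rather than silently
  producing constants.
* Multi-year headline figures ("X ± Y Mt yr⁻¹ over a period") are the mean
  and n−1 SD of the *annual mean* estimates; the alternative pooled-run
  reading is computed behind `method = "pooled_runs"` and labelled, since
  the two can differ materially when annual means trend.
* The convergence study declares stabilisation when the inter-iteration SD
  of the grand mean falls below 1% of the mean (10 independently seeded
  iterations per run count) — our operationalisation of "output
  stabilised".
* Internal arithmetic is in kg; user-facing summaries are in Mt (10⁹ kg).

## Geometry

Coordinates are planar, in a projected equal-area CRS (EPSG:3035 for the
Northwest European Shelf); ingestion is expected to reproject. Distance to
the coastline is Euclidean point-to-segment distance, which differs
negligibly from geodesic distance at the ≤ 5 km scale of the coastal
filter. Point-in-polygon overlay uses `mgcv::in.out()`, cross-checked in
the test suite against an independent brute-force ray-casting oracle on
randomly scattered points. Substrate maps and coastlines are read and
written as GeoJSON FeatureCollections (via jsonlite); polygon rings must be
closed, finite, and have at least four vertices — self-intersection is not
checked.

## The synthetic-data generator

The generator exists so every pipeline stage is testable without any
external download. It emulates:

* a coastal %TOC pool drawn from a log-normal solved by quantile inversion
  to hit a (median, p95) target of (1.78, 6.46) %TOC, n = 9920 — the
  published structure of the coastal pool this analysis style rests on;
* per-substrate pools of 7262 sand, 720 coarse and 273 mixed samples with
  class targets (0.46, 5.1), (0.62, 5.8) and (0.85, 6.5) %TOC, chosen once
  so that the count-pooled combined distribution lands near its published
  (0.48, 5.19) structure;
* decoy samples in *every* excluded category (saltmarsh, seagrass, above
  mean high water, beyond the offshore cutoff) so each filter's effect is
  independently assertable;
* a straight coastline with a sand/coarse/mixed checkerboard starting 5 km
  offshore — extraction licence areas sit offshore, so inshore samples fall
  outside every substrate polygon;
* event tables whose records carry a true mass drawn from the log10-normal
  (μ = 7.2, σ = 0.69 log10 kg) and report it as a random unit, as a cost
  (at a configured true rate), or not at all, with the 6/57/54-of-117
  composition of the historical UK port returns as the default missingness
  mix;
* ground-truth records (true masses, true classes, true coast distances)
  so imputation and classification error are measurable.

The log-normal family was chosen for %TOC because the values are positive
and right-skewed with median ≪ mean; values are clipped to [0, 100].

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: spatial autocorrelation of %TOC, realistic
coastline geometry or substrate patchiness, reporting biases and gaps in
voluntary registries, screening losses in aggregate extraction (landed
cargo understates disturbed sediment), currency deflation across historical
cost records, and between-method variability in %TOC measurement. Tests
demonstrate that the estimator machinery is correct under the stated
assumptions, not that those assumptions hold in any particular sea.

## Default problem sizes

The test suite and the acceptance script run the full-size %TOC library
(9920 + 8255 samples plus decoys) but keep event tables small (tens to
hundreds of events) and use 10,000-run simulations only where the quantity
reported depends on it, with smaller run counts (500–2000) for
property-style checks where Monte Carlo error bounds are asserted
explicitly. These sizes make the whole suite run in well under a minute
while leaving every statistical tolerance derived from first principles
(CLT standard errors, binomial spread), not tuned to the draw.

## Known limitations

* Cost-based imputation applies a single average rate with no currency
  deflation across the historical window, matching the single-rate design
  it reproduces; a documented simplification.
* The sparse-year filter and category exclusions assume the relevant
  metadata (`country`, `category`) are populated; records with missing
  categories are retained.
* Empirical resampling cannot extrapolate beyond observed %TOC values; if
  the sample library under-covers carbon-rich estuarine sites, estimates
  inherit that bias.
* `aggregate_ports_to_nation()` and `aggregate_country_to_shelf()` require
  retained run totals (`keep_runs = TRUE`); summaries alone cannot be
  aggregated exactly because percentiles are not additive.
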