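---
title: "Methods: source-attributed health burden and damage functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-attributed health burden and damage functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourceburden)
```

## The model

`sourceburden` attributes premature-mortality burden to emitting
(state, sector, precursor) sources. Its inputs are *sensitivity surfaces*:
gridded fields `Δx` giving the change in ambient PM2.5 (µg/m³, monthly
mean of 24-hr averages) or O3 (ppb, monthly mean of daily 8-hr maxima)
per cell attributable to a tagged source's emissions. Eight
precursor–pollutant relationships are modeled: PEC, POC, PSO4 (primary
PM2.5), NOx, SO2, VOC (secondary PM2.5), and NOx, VOC (O3). Sensitivities
are signed — January NOx→O3 surfaces are negative where fresh NO consumes
ozone (titration).

Mortality follows the standard linear health-impact equation

$$\Delta y = \sum_{i=1}^{N}\sum_{j=1}^{M} y_{0,ij}\,\beta\,\Delta x_{ij}\,Pop_{ij},$$

where `y0` is the cell's baseline annual mortality incidence rate for
adults ≥ 25, `β` the concentration–response function, and `Pop` the cell's
adult population. The model is deliberately a rate difference, not a
log-linear relative risk: impacts are then exactly linear in `β`, `Δx` and
`Pop`, which the test suite verifies to 1e-12 relative tolerance and which
makes attribution additive across sources.

Two months stand in for the year. January and July each represent six
months: a month's surface yields an *annual-rate* impact (as if its
conditions persisted all year), the half-year impact is half of that, and
the annual impact is the sum of the two half-years — equivalently the mean
of the two annual rates. The same convention produces damage functions:
a month's annual-rate deaths divided by annualized emissions (monthly tons
× 12), times 1,000, gives deaths per 1,000 tons under that month's
conditions; the annual damage function is the arithmetic mean of the
January and July values, interpreted as the risk of emissions spread
uniformly over the year. Damage functions keep their sign, so a negative
January NOx→O3 value averages through zero against a positive July one.

### Concentration–response functions

| pollutant | default β | meaning |
|---|---|---|
| PM2.5 | 0.01 per µg/m³ | 1% mortality increase per 1 µg/m³ annual average |
| O3 | 0.0004 per ppb | 0.4% increase per 10 ppb daily 8-hr maximum |

The O3 coefficient is an acute (daily) estimate from year-round studies;
applying it to annual baseline mortality with the monthly mean of daily
8-hr maxima is equivalent, under a constant fractional effect, to summing
daily impacts. Both betas are single central estimates — uncertainty
intervals are intentionally out of scope, and because the model is linear
any alternative β rescales results without changing relative comparisons.
Annual (not month-specific) baseline mortality is used for both pollutants
and both months; month-resolved baseline rates are not modeled.

## Separation of composite surfaces

Tagging several states in one model run is cheap but yields a composite
surface; attribution requires splitting it. `region_grow()` implements
seeded best-first region growing:

* **Seeds** (`select_seeds()`): each member state's seed is the cell of
  maximum composite `|Δx|` within its emission footprint dilated by one
  cell, ties broken by smallest `(i, j)`. An all-zero footprint
  neighborhood falls back to the footprint's maximum-weight cell and is
  flagged rather than rejected.
* **Growth**: one frontier entry per (cell, claiming state), priority the
  cell's `|Δx|`. The globally largest-priority cell is popped (ties again
  by smallest `(i, j)`) and labeled with its claiming state, after which
  it claims its unlabeled 8-neighbors above the background floor.
  Magnitudes, not signs, drive growth, so an all-negative titration field
  segments identically to its positive mirror — regions may contain mixed
  signs when the physics produces them.
* **Contested cells**: a cell claimed by two or more states before its pop
  becomes `OMITTED` and never propagates growth. This deliberately
  sacrifices a thin ridge of cells along inter-plume valleys to guarantee
  that each state's region is clean, 8-connected, and contains its seed.
  The omission is a documented downward bias, policed by QA (below).
* **Background**: cells with `|Δx|` below the floor — default `1e-6 ×
  max|Δx|`, a relative floor so behavior is scale-free — are labeled
  `BACKGROUND`; above-floor cells unreachable from any seed also fall to
  background.

The exact growth rule is this package's own reconstruction from the
constraints such a separation must satisfy (contiguous per-state regions,
signed cells includable, small states able to capture their full extent,
deterministic output). Determinism is strong: pop order depends only on
`|Δx|` and the lexicographic tie-break, so permuting the member list
leaves the label map bit-identical (tested).

For runs whose member plumes do not overlap above the floor, the label map
provably equals the *dominant-contributor oracle* (label each cell by the
member with the largest ground-truth `|Δx|`); for overlapping
equal-amplitude plumes the contested ridge coincides with the oracle's
exact-tie set. Both facts are exercised in the tests.

### QA gate and fallback

`qa_run()` measures the omission fraction as omitted health-impact
magnitude over total non-background health-impact magnitude (per-cell
`|y0·β·Δx·Pop|` summed). Impact rather than concentration mass is the
basis because the quantity being protected is deaths, and a contested cell
over empty land costs nothing. A run passes when the fraction is below the
threshold (default 0.10); failing runs fall back to singleton per-state
surfaces — in synthetic mode the stored ground truth, mirroring the
practice of re-running a failing group one state at a time. A run with
zero total non-background impact is degenerate; its fraction is defined
as 0 and flagged.

## Exposure gridding

`intersect_to_grid()` apportions county adult population to cells in
proportion to intersected area (uniform density within counties), and sets
each cell's baseline rate to the population-weighted mean of its
contributing counties' ten-year average rates — the weighting is this
package's choice for fractional cells, and zero-population cells carry a
rate of 0 by convention so no weighted mean is undefined. Intersection
areas come from clipping the county polygon to each cell rectangle
(Sutherland–Hodgman) with shoelace areas, implemented in the package;
this is exact for rectangular counties and correct for any simple
polygon. Population is conserved exactly for rectangular tilings (tested
over random scenarios at 1e-9) and each cell's rate is bounded by its
contributors' rates.

## The synthetic scenario generator

`generate_scenario()` produces everything a run of the pipeline needs,
with exact analytic ground truth:

* **Plumes** (`generate_plume()`): isotropic Gaussian kernels of spread σ
  centered at each footprint cell displaced by a fixed advection offset,
  scaled by tons × seasonal multiplier × amplitude-per-ton. Amplitude is
  exactly linear in emissions; composites are exact element-wise sums of
  member ground truths, so attribution error is measurable, not assumed.
* **Seasonality**: scalar amplitude multipliers per (sector, pair) —
  defaults give RC primary PM2.5 a 20:1 January:July contrast, EGU
  SO2→PM2.5 a 5:1 July:January contrast, and NOx→O3 a negative January /
  positive July pair for both sectors (`default_seasonal_profiles()`).
  A scalar multiplier reproduces the intended seasonal impact ratios
  exactly while keeping ground truth analytic.
* **Counties**: a near-square rectangular tiling covering the domain
  exactly; populations log-uniform in 5×10³–2×10⁶, ten yearly rates
  uniform in 0.008–0.015 /person/yr — plausible for an adult ≥ 25
  population at county scale.
* **Default study conditions**: a 40 × 60 grid of 36-km cells; six states
  paired into three two-state run groups per sector; footprint centers 9
  cells (324 km) apart within a pair; RC plumes σ = 54 km from 3 × 3 area
  footprints, EGU plumes σ = 90 km from single-cell point footprints
  (secondary formation spreads farther); eastward advection offsets;
  state emissions scaled by deterministic factors 0.7–1.7 around realistic
  tonnage (e.g. 16,000 t/month EGU SO2 vs 350 t/month RC SO2). All
  randomness flows from the single scenario seed; regeneration is
  bit-identical, and the whole pipeline re-run under a fixed configuration
  reproduces its output bundle byte for byte (tested via checksums).

What the generator does **not** emulate: real state geographies, wind
fields and chemistry, mixed-sign microstructure within a single source's
surface (mixed-sign test fields are made by summing opposite-sign
plumes), emission inventories, or population clustering within counties.
Passing tests therefore demonstrate the correctness of the attribution
machinery under controlled overlap and seasonal structure — not the
fidelity of any particular atmospheric simulation.

Synthetic states also need receptor boundaries for within-source-state
fractions; `state_masks()` assigns each cell to the nearest footprint
center (a Voronoi partition), which is why default within-state fractions
are high compared to real mid-continent states.

## Damage-function summaries

`flag_low_emission()` marks, per (sector, pair) group, the five
lowest-emitting states (ties by state id, clamped to group size) and any
state under an absolute floor (default 1 ton/yr) — tiny emissions produce
abnormally inflated deaths-per-ton values, and both the rank-based and
absolute pathologies must be expressible; whether ranking is per pair or
per sector overall is configurable (`per_pair`). Flagged rows are kept in
the table but excluded from percentiles. `summarize_burden()` reports the
5th percentile, quartiles, and 95th percentile across unflagged states
using linear interpolation between order statistics (R `quantile`
type 7 — the definition is stated because several exist; tests check it
against an independent interpolation oracle), plus per-state EGU:RC annual
death ratios with zero denominators reported as missing.

## Numerical and interface conventions

* Grid indexing is 1-based `(i = row, j = col)` with row 1 the
  southernmost row and the origin at the lower-left corner — the native R
  convention; the grid is an abstract planar equal-area plane with no
  geographic projection.
* CSV field files carry a `# key=value` header and 17-significant-digit
  values so write/read round trips are exact to 1e-12; NetCDF I/O
  (dimensions row/col, variable `delta_x`, metadata as global attributes)
  is available when `ncdf4` is installed and cross-checked against CSV.
* Configuration files are YAML, sectioned per scenario override; a run
  manifest records the configuration hash and seed.
* Exact ties (seed selection, pop order, low-emission ranking) always
  break lexicographically, which is what makes every stage
  permutation-invariant and reproducible.
* Degenerate inputs are contracts, not errors: zero-emission sources give
  all-zero fields; zero-impact runs give flagged degenerate QA reports;
  zero-emission damage functions are `NA` with the flag set; empty
  receptor masks give 0%.

## Problem sizes

The shipped defaults — 2,400 cells, 96 composite surfaces per fit, 48
counties — keep a full fit around two seconds and the entire test suite
under half a minute, while leaving every overlap and seasonality regime of
interest represented. Larger grids change nothing structurally: every
algorithm is O(cells · log-ish) per surface.

## Known limitations

* The separation algorithm is a faithful-by-constraints reconstruction;
  other growth rules satisfying the same constraints would draw slightly
  different contested ridges.
* The omitted share is a downward bias on totals and can be relatively
  larger for an individual small state within a multi-state run.
* Uniform density within counties misplaces exposure where population is
  strongly clustered; the effect is modest at 36-km cells but grows for
  primary pollutants with small impact footprints.
* No uncertainty propagation: CRFs and plume parameters are point values;
  all results scale linearly in β.
* The half-year convention assumes two months represent their seasons;
  the generator makes this exact by construction, real data would not.
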