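---
title: "Scenario modelling of valley corridors and conflict risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario modelling of valley corridors and conflict risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`corridorsim` chains four models — landscape change, habitat permeability,
stochastic least-cost-path connectivity, and conflict risk — into one
seeded pipeline. This vignette documents each model's assumptions, the
parameters that matter, the numerical choices, and what the synthetic
valley does and does not establish about real landscapes.

## The landscape model

A landscape is a grid of 100 m cells (the default study area is 200 × 450
cells ≈ 900 km²), each carrying cover *fractions* that sum to one. Natural
classes (forest, shrub, alpine, water) describe the pristine composition;
anthropogenic classes (linear, recreation facility, settlement, industrial,
farmland) enter as dated *footprint events*, each a set of cells converted
in a known origin year. The composed landscape scales the natural mix of a
cell by one minus its total footprint fraction, so composition is always a
pure function of (pristine mix, events up to the year). Two consequences:

- **Backcasting is lossless.** Removing events younger than a target year
  and re-applying them reproduces the current raster bit for bit, for any
  event subset. The tests assert this as an exact identity rather than a
  tolerance comparison.
- **Area accounting is exact.** Class areas are fraction sums times cell
  area, so per-class areas and the footprint total are additive by
  construction.

Forecasting converts whole cells to 100 % settlement, matching the grain of
the cost surface and keeping areas exact. A 30-year growth fraction *g* is
applied as a per-decade multiplier $(1+g)^{1/3}$; with the defaults (rural
0.61, growing town 0.87, park townsite 0) a 100-cell town reaches 187 ± 1
cells after three decades. The town fraction 0.87 is used directly because
the corresponding population projection (0.97) is partly absorbed by infill,
which the model does not represent. Town growth is allocated outward from
the town centre, exhausting the growth-boundary ring before the
area-to-be-determined zone east of town; rural growth samples candidate
cells 8-adjacent to existing settlement with weight proportional to the
adjacent patch size (power-law exponent 1, configurable — the functional
form of this bias is a modelling choice, not an estimated quantity).

## Permeability and the cost surface

Habitat permeability follows a resource-selection-style log-linear model:
cover-fraction terms plus elevation (km), slope (rise/run) and
distance-to-footprint (km). $\exp(\eta)$ is min–max normalized to [0, 1]
with bounds fixed on the current-year landscape, so historical and future
surfaces share one scale and remain comparable; a degenerate (constant)
predictor maps to permeability 1 everywhere, by documented convention.
Published regional coefficients are not available as redistributable
inputs, so the package ships a *synthetic default* coefficient table that
encodes the qualitative structure the analysis needs — selection for
valley-bottom forest/shrub, avoidance of elevation, slope and all
development classes. Magnitudes were chosen to keep the predictor range to
roughly three log units: with much larger ranges, exponentiation followed
by min–max normalization saturates (almost every cell maps near zero
permeability), which destroys the valley/midslope/development contrast the
corridor model depends on. User-fitted coefficient tables plug in through
`permeability_model()`.

Cost is $1 - \pi$ after two highway modifications: permeability is
multiplied by $\min(d/500\,\mathrm{m}, 1)$, a linear road-avoidance decay,
and highway cells are removed from the movement graph entirely except at
wildlife crossings whose construction year has passed. The synthetic
default includes one pre-1970 crossing so that early landscapes are
crossable at all; remaining structures open in 1988, 1997, 2014 and 2027.

## The path ensemble

Movement is modelled on the 8-connected grid graph. An edge's weight is its
geometric length (100 m cardinal, 100√2 m diagonal) times the mean cost of
its two endpoint cells, plus a floor of 10⁻⁹ so zero-cost corridors still
have unique finite geodesics; this is the standard accumulated-cost-surface
convention. Equal-cost ties break deterministically by predecessor scan
order, which is immaterial in production because the Normal perturbation
makes exact ties measure-zero.

Start and end cells (100 + 100 by default) are drawn without replacement
from cells holding at least two collar locations. Each of the 10 iterations
redraws every cell's cost from Normal(cost, σ) with σ equal to the
study-area standard deviation of cost — selection is not assumed optimal —
truncated below at 10⁻⁶ because negative costs break shortest-path
semantics. One redrawn surface is shared by all pairs of an iteration,
which both matches the iterate-then-pair description of the design and
allows a single single-source computation per start point. The result is
100 starts × 100 ends × 10 iterations = 100,000 paths per landscape; pairs
disconnected on a perturbed surface (possible only when no crossing is
open) are dropped from the denominator with a warning.

Per-cell path proportions are heavily right-skewed, so the 0–5 connectivity
index uses geometric bin edges $t_k = p_{\max}/r^{5-k}$, $k = 1..5$, with
ratio $r = 4$ and the anchor at the maximum observed proportion; level 0 is
reserved for cells never crossed, and level $k$ covers $(t_{k-1}, t_k]$
with $t_0 = 0$. Anchoring at $p_{\max}$ (rather than a fixed constant) is a
design choice that keeps the index comparable across landscapes whose
absolute proportions differ.

## Recreation activity

Activity levels 0–5 map to absolute use through $A(k) = A_0 g^{k-1}$
(level 0 ↔ exactly zero use). The growth factor defaults to $g = 3$: the
exponential form is the modelled relationship, but its base was originally
calibrated against trail-count data that is not redistributable, so the
scale is exposed as a free parameter with an order-of-magnitude default.
The floor-log inverse uses a 10⁻⁹ slack before truncation so representable
levels round-trip exactly.

Backcasting applies two rules: activity inside recreation facilities or
within 2 km of settlement is zeroed wherever that footprint postdates the
target year (it is assumed to be generated by the development), and the
remainder is rescaled by a single regional factor so total activity growth
to the present equals the configured population growth. The default
trajectory (growth of 4.0, 1.5, 0.8 and 0.35 from 1970, 1990, 2000 and
2010 to the present) is a synthetic stand-in shaped like the region's
population history. Forecasting adds, per growing municipality and decade,
new activity equal to the population-growth fraction of the municipal
total: half intensifies existing trails proportionally to current use, half
is placed on new random-walk trails within 2 km of new settlement cells
(clipped to the municipal zone so the decadal mass balance is exact to
numerical precision). The park townsite intensifies existing trails by 25 %
per decade and gains no new trails.

Scenario rules act on the forecast: *no informal trails* zeroes activity
off designated trails and off footprint; *restricted recreation* halves
activity at distance ≥ 100 m from settlement (the boundary cell at 99 m is
untouched); *limited urban expansion* is implemented upstream, scaling the
growing town's footprint and activity growth inputs to 15 % and closing the
area-to-be-determined zone.

## Conflict risk

Risk is the cell-wise product of the 400 m circular moving-window means of
the connectivity index and the activity level, hence ranges over [0, 25].
The window is a *radius* (the buffer it descends from is a radial concept);
this is flagged in configuration because a diameter reading would halve it.
Windows shrink at the grid edge instead of padding with zeros, so boundary
averages are unbiased. Categories: (9, 25] high, (4, 9] moderate, (1, 4]
low, (0, 1] very low, and a fifth "none" code for exactly zero — the
boundary semantics (9 → moderate, 9.01 → high) are asserted in the tests.
Extents are cell counts times cell area, and mitigation scenarios are
compared through the percent change of the combined moderate-or-high
extent against the Base Case of the same year.

## The synthetic valley: what it does and does not show

The generator reproduces the *statistical structure* the analysis assumes:
a U-shaped valley (parabolic cross-section plus a smoothed random field),
elevation-banded natural cover, footprint concentrated on the valley bottom
(3–8 % of the study area; 4.4 % on the default seed), towns that straddle
the highway and stretch across the valley floor the way real valley
townsites do, dated footprint in five eras, > 80 % of absolute activity
within 2 km of settlement, and collar points biased toward permeable
natural habitat. Trails carry an off-trail "halo" of diffuse activity,
emulating the areal footprint of a heatmap product rather than bare
polylines.

Passing tests on this landscape establish that the machinery is correct
(exact path optimality against exhaustive enumeration, barrier soundness,
mass balances, round trips, determinism) and that the qualitative
mechanisms operate: corridors displace upslope when settlement is added,
and moderate/high risk extent grows along the Base Case timeline. They do
*not* establish the published regional magnitudes — real terrain,
vegetation, visitation totals and fitted selection coefficients are absent,
so scenario reduction percentages on the synthetic valley (for example
86 % for eliminating informal trails at the test scale) are not estimates
of the real-data values.

One behavioural claim deserves care: for the two activity-side scenarios,
risk-extent dominance over the Base Case is mathematically guaranteed
(connectivity is identical and activity is reduced cell-wise), and the
tests assert it strictly. For *limited urban expansion* the sign is
genuinely empirical: less settlement growth removes activity but also
leaves corridors nearer the valley bottom — and town — so the net effect on
overlap fluctuates with Monte Carlo corridor noise at small ensemble sizes.
The tests therefore assert the scenario's deterministic guarantees (less
footprint, less activity than the Base Case every forecast year) and the
acceptance script reports, rather than asserts, its extent comparison.

## Problem sizes and reproducibility

The default ("full") profile uses the 900 km² valley with the
100 × 100 × 10 sampling design. The test profile — used throughout the test
suite and by the acceptance script — runs the identical code on a 50 × 80
valley with 20 starts, 20 ends and 2 iterations (10 for the behavioural
checks), chosen so a complete multi-scenario run takes seconds while still
exercising every stage, including the highway barrier and staged growth
zones. A single top-level seed derives per-stage substreams, so any
configuration reruns bit-identically; the output manifest records per-file
md5 hashes to make this checkable.

Known limitations: no circuit-theory (current-flow) connectivity, no
winter selection model, no attractant or vehicle-collision risk, no
agent-based recreation or trail-formation dynamics, no densification or
demolition of footprint, and no geographic reprojection — rasters live in
one planar metric frame.
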