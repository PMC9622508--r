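# corridorsim

Cumulative-effects scenario modelling of grizzly bear movement corridors and
human–bear conflict risk in a mountain valley.

Project-scale environmental assessment rarely captures what decades of
settlement growth and recreation do to wildlife movement. `corridorsim`
implements that regional, multi-decade analysis as a reproducible pipeline
for landscape ecologists and land-use planners:

1. **Landscape simulation** — a current landscape (per-cell cover fractions
   at 100 m grain, with dated footprint patches) is *backcast* to historical
   years by removing footprint younger than the target year, and *forecast*
   by rule-based settlement expansion (rural +61 %/30 yr, the growing town
   +87 %/30 yr allocated outward from the town centre through staged growth
   zones, the national-park townsite fixed).
2. **Movement connectivity** — a resource-selection-style habitat model
   gives each cell a permeability π ∈ [0, 1]; the traversal cost is
   c = 1 − π, with permeability additionally scaled by min(d/500 m, 1) near
   the highway, and the highway itself an absolute barrier except at dated
   wildlife crossings. Least-cost paths are sampled between 100 start and
   100 end cells drawn from collared-bear locations, over 10 iterations in
   which every cell cost is redrawn from Normal(c, sd(c)) (truncated at
   10⁻⁶), giving 100,000 paths per landscape. Per-cell path proportions are
   binned into a 0–5 connectivity index on geometric bin edges
   t_k = p_max / r^(5−k) (r = 4).
3. **Conflict risk** — recreation intensity is a 0–5 level raster tied to
   absolute activity by A(k) = A₀·g^(k−1); risk is the product of the 400 m
   moving-window means of the connectivity and activity levels, classified
   as very low (0, 1], low (1, 4], moderate (4, 9], high (> 9].
4. **Scenarios** — a business-as-usual Base Case and three mitigations:
   *limited urban expansion* (town growth inputs cut to 15 %, the eastern
   expansion zone closed), *no informal trails* (activity eliminated off
   designated trails and off footprint), and *restricted recreation*
   (activity halved at least 100 m from settlement).

A synthetic-valley generator supplies statistically realistic inputs — a
U-shaped valley, footprint concentrated on the valley bottom, a fenced
highway with sparse crossings, more than 80 % of recreation within 2 km of
settlement, and collar points clustered in permeable habitat — so the whole
pipeline runs without any proprietary GIS, collar or fitness-tracker data.

## Worked example

```r
library(corridorsim)

res <- run_pipeline(run_config("test", rng_seed = 1, n_iter = 10))
mh  <- attr(res$extents, "mod_high")
subset(mh, year %in% c("1970", "2020", "2050") & scenario == "base")
#>    year scenario  km2 pct_change_vs_base
#>    1970     base 1.90                  0
#>    2020     base 7.96                  0
#>    2050     base 8.55                  0
subset(mh, year == "2050" & scenario != "base")
#>    year                scenario  km2 pct_change_vs_base
#>    2050 limited_urban_expansion 7.75          -9.356725
#>    2050      no_informal_trails 1.20         -85.964912
#>    2050   restricted_recreation 6.86         -19.766082
```

The `km2` column is the combined moderate-or-high conflict-risk extent. On
this synthetic valley the extent roughly quadruples between 1970 and today
and keeps growing in the Base Case forecast; eliminating informal trails is
the strongest mitigation because informal trails concentrate where
corridors squeeze past the towns, mirroring the qualitative behaviour of
the regional analysis the model family was built for. Rasters, summaries
and a hash manifest can be written by passing `workdir =` to
`run_pipeline()`, or from a shell via the thin `exec/corridorsim` wrapper
(`corridorsim simulate --seed 1 --out outdir`).

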