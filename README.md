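# heatvuln

Commune-level heatwave vulnerability scoring and heat-morbidity
surveillance for R.

## The problem

General practitioners and public-health teams need to know *where* heat
will hurt most before a heatwave arrives. Mortality data are not
available at fine spatial resolution, so vulnerability has to be
modelled from structural indicators. `heatvuln` builds a mappable index
at the scale of the smallest administrative unit (the French commune,
mean area 14.9 km²) from four layers:

| indicator | source format | orientation |
|---|---|---|
| mean summer surface temperature (°C) | daily rasters | risk |
| deprivation score (FDep-style PCA of 4 socioeconomic variables) | CSV | risk |
| artificial + non-vegetated surface fraction (CORINE codes) | land-cover raster | risk |
| air-conditioning equipment rate of primary residences (%) | CSV | protective |

Each indicator is standardised as a Z-score over all scored units
(population convention) and combined with equal weights:

    V_i = (z_temp + z_fdep + z_artif − z_ac) / 4

Units are then classed into quintiles for choropleth mapping. A
companion indicator aggregates emergency-department and emergency-GP
visits for hyperthermia/heatstroke, dehydration and hyponatremia into
per-unit counts and rates per 10 000 residents.

Because the real inputs are national administrative products, the
package ships a fully seeded synthetic generator (commune grid,
urban-heat-island temperature field, CORINE-coded land cover, one-factor
socioeconomic table, AC rates, Poisson visit records) with known latent
structure, so the entire pipeline is testable and demonstrable without
any download. See `vignettes/heatvuln-methods.Rmd` for the full model
and every design choice.

## Worked example

```r
library(heatvuln)

cfg <- synth_config(seed = 1)          # 10 x 10 communes, cell side sqrt(14.9) km
res <- run_pipeline(run_config("demo_out", synth = TRUE, synth_cfg = cfg))
s   <- res$scores
head(s[, c("unit_id", "z_temperature", "z_fdep", "z_artificial", "z_ac",
           "index", "quantile_class", "n_visits", "rate_per_10k")], 5)
```

```
  unit_id z_temperature z_fdep z_artificial   z_ac   index quantile_class n_visits rate_per_10k
1   01001        -1.267 -0.376       -1.270  0.533 -0.8614              1        0         0.00
2   01002        -0.954 -0.181       -0.948 -1.940 -0.0358              3        0         0.00
3   01003        -0.876  0.780       -0.881 -0.140 -0.2094              2        0         0.00
4   01004        -0.617  0.376       -0.613 -0.304 -0.1377              3        1         4.16
5   01005        -0.817  0.348       -0.811 -1.091 -0.0474              3        2         6.42
```

Unit `01001` is an edge commune: cool (`z_temperature` −1.27), rural
(`z_artificial` −1.27) and not notably deprived, so its index −0.86
lands in the lowest vulnerability quintile. The 100 units split 20/20/
20/20/20 across the five classes, and the Spearman correlation between
the index and the per-capita visit rate on this run is 0.247 — positive,
as the generator's visit model implies. `demo_out/` contains
`scores.csv`, `icanicule.csv`, `vulnerability.geojson` (polygons with
all attributes) and `manifest.json` (per-stage counts, warnings,
checksums). `export_choropleth()` renders the classed map to PNG +
GeoJSON.

A command-line front end covering every stage (subcommands `synth`,
`zonal-temp`, `landcover`, `fdep`, `index`, `icanicule`, `run`,
`export`) is installed at `system.file("cli", "heatvuln.R", package =
"heatvuln")`.

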