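---
title: "Methods: constructing a commune-level heatwave vulnerability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing a commune-level heatwave vulnerability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Heatwave vulnerability varies strongly between small administrative
units: exposure is driven by the urban heat island, while the capacity
to cope depends on social deprivation and on access to air conditioning.
`heatvuln` scores each unit (commune) with an equal-weight composite of
four indicators:

* **mean summer surface temperature** (°C), reduced from daily rasters —
  a risk factor;
* **deprivation score**, an FDep-style first principal component of four
  socioeconomic variables — a risk factor;
* **artificial and non-vegetated surface fraction** from a CORINE-coded
  land-cover raster — a risk factor (vegetation is protective, so its
  complement enters as exposure);
* **air-conditioning equipment rate** of primary residences (%) — the
  single protective factor.

Each indicator $x$ is standardised over all scored units as a Z-score
$z_i = (x_i - \mu)/\sigma$ (population convention, divisor $n$), and the
composite index is

$$V_i = \tfrac{1}{4}\,(z^{temp}_i + z^{fdep}_i + z^{artif}_i - z^{ac}_i).$$

Equal weights are deliberate: no outcome data exist at this resolution
to fit weights defensibly, and an unweighted mean keeps the index
auditable. Division by 4 (rather than a raw sum) keeps $V$ on a z-like
scale; the two are rank-identical. Orientation is carried as data on
every `indicator_column`, so the signs in the formula are checked, not
assumed. Z-scores are computed over the full national (or fixture) unit
set rather than per department, because the map's purpose is comparison
across departments.

The companion morbidity indicator counts emergency-department and
emergency-GP visits for the four heat-related causes — hyperthermia and
heatstroke, dehydration, hyponatremia — per unit and period, with a rate
per 10 000 residents. It is reported both as a count and as a rate;
neither is endorsed as canonical, because surveillance practice uses
both. No small-count smoothing is applied: small-area counts are noisy,
and any disease-mapping model would change the indicator's meaning.

## Zonal statistics

Raster layers are reduced to unit level with a **pixel-centre rule**: a
pixel belongs to the unit whose polygon contains its centre; a centre
exactly on a shared boundary goes to the unit earliest in lexicographic
`unit_id` order. This rule is exact, deterministic under any unit
ordering, and trivially auditable against a brute-force pixel loop —
which the test suite does. At 100 m pixels against ~15 km² communes the
discretisation error relative to area-weighted overlap is negligible.

Daily temperature rasters are averaged over time first (ignoring nodata
days per pixel) and reduced zonally second. The two orders commute only
without nodata, so the order is fixed and stated. Units with no valid
pixel are flagged missing, never zero-filled — 0 °C is a valid
temperature.

Vectors and rasters must declare the same reference system; rasters are
never silently reprojected or resampled, because resampling temperature
or class codes changes results invisibly. Vector input in geographic
coordinates is reprojected to a local equirectangular metre projection
(the working projection is a configuration item, not an inference).

## Land-cover grouping

CORINE codes are grouped as: 111–142 artificial; 331–335 open spaces
with little or no vegetation; 211–324 vegetated (agricultural, forest,
semi-natural); 411–523 wetlands and water. The exposure numerator is
artificial + non-vegetated open; water is excluded from the numerator
but kept in the denominator, so a lakeside commune is not inflated to
look urban. Whether water should leave the denominator entirely is a
legitimate alternative reading; the grouping ships as a plain-text
config (`inst/extdata/corine_grouping.cfg`) so that reading is one edit
away.

## The deprivation score

The four components — unemployment rate, % blue-collar workers (both
among the active population 15–64), % high-school graduates (≥15), and
median household income — are standardised (population convention) over
complete cases and projected on the leading eigenvector of their
correlation matrix. The correlation (not covariance) matrix is used
because the components carry incommensurable units; consequently the
score is invariant to any positive rescaling of a component (tested with
a currency change). Eigenvectors are sign-ambiguous, so the sign is
anchored to make the score correlate positively with unemployment:
higher = more deprived. Two numerically equal leading eigenvalues
(within 1e-9) abort with an instability error rather than returning an
arbitrary component. The module recomputes the construction from
components; it does not reproduce any official national release, and
labels its output fdep-like.

Incomplete units are excluded from the eigen-decomposition and scored
missing. The index stage then applies the imputation policy —
`department_median` by default, for the deprivation score only:
socioeconomic missingness is administrative and departments are the
natural pooling unit, whereas temperature or land-cover missingness is
structural (no valid pixels) and is left missing. `neighbour_mean`
(polygon-adjacent units, boundaries within 1 m) and `drop` are
available. Every imputation raises a warning and is flagged in the
output, because the index silently depends on it.

## Quantile classes

For mapping, scores are classed into $k = 5$ quantile bins (quintile
choropleths are the convention for heat-vulnerability maps;
configurable). Breaks are linear-interpolation quantiles
(`stats::quantile` type 7) with inclusive upper edges, so distinct
values split into classes whose sizes differ by at most one. Fewer
distinct values than $k$ collapse to distinct-value classes with a
warning rather than inventing empty bins.

## What the synthetic generator emulates

Because the real inputs are national administrative products, the
package carries a fully seeded generator whose defaults define the
reference study conditions:

* a 10 × 10 grid of square communes with side $\sqrt{14.9}$ km, so every
  cell has exactly the national mean commune area of 14.9 km²;
  departments in bands of three grid rows; log-normal populations
  (median ≈ 1500, a mix of villages and towns);
* a radial urbanisation gradient (artificial fraction ≈ 0.9 at the
  centre, 0.05 at the edge, Gaussian jitter SD 0.02) — the latent
  driver of both land cover and temperature;
* surface temperature = 22 °C baseline + 3 °C × artificial fraction
  (a typical urban-heat-island amplitude) + pixel noise SD 0.5 °C, on
  100 m pixels, 7 daily rasters with a small deterministic day-to-day
  wobble;
* a one-factor deprivation model: latent $d_i \sim N(0,1)$, components
  = loading × $d_i$ + $N(0, 0.5)$ with loadings (+1, +1, −1, −1), then
  fixed affine maps onto realistic scales (affine maps leave the
  correlation-matrix PCA unchanged, so zero-noise recovery is exact);
* AC rate = 15% + 2 percentage points per °C above baseline + noise
  SD 3, clipped to [0, 100] (clipping is applied after the noise so the
  bound always holds; at zero noise this equals the unclipped formula);
* visit counts per commune $\sim$ Poisson(population/10 000 × 5 ×
  exp(0.5 × standardised true vulnerability)), causes uniform over
  {T67.0, T67.9, E86, E87.1}, source ED/GP with probability 0.7/0.3,
  dates uniform over June–August 2022.

Each generator draws from its own stream derived from (seed,
generator-name), so adding a generator never perturbs another's output,
and fixtures are stable across versions. The latent quantities
(artificial fraction, deprivation factor, true vulnerability) are
returned as clearly test-only ground truth for recovery checks.

The generator does **not** mimic real commune shapes, real CORINE
mosaics, spatially autocorrelated deprivation, seasonal temperature
trends, or realistic emergency-visit volumes. Passing tests therefore
demonstrate that the pipeline computes its definitions correctly and
recovers known latent structure — not that the index is validated
against real heat-morbidity outcomes, which the equal-weights design
explicitly leaves open.

## Numerical choices and degenerate inputs

* Point-in-polygon uses the even-odd rule over all rings (holes
  supported) with boundary points counted inside; the tie-break then
  resolves shared boundaries deterministically.
* Z-scoring and component standardisation require ≥ 2 values (≥ 5
  complete cases for the PCA) and non-zero dispersion; constant columns
  are a `degenerate-variance` error, never silently dropped.
* Composite scores are reproduced by an independent re-evaluation of
  the formula to 1e-12 in the tests; affine invariance of $V$ holds to
  1e-9.
* CSV outputs are written with a fixed 12-significant-digit format so
  repeated runs are byte-identical.
* Problem sizes in the test suite: 10 × 10 communes at 100 m pixels for
  the zonal oracle, n = 500 for deprivation recovery, 50 visit
  replicates for the morbidity association — sizes at which every
  brute-force oracle is exact and the whole suite runs in seconds.

## File formats

Vector layers are GeoJSON (attributes `unit_id`, `name`,
`department_id`, `population`); unit identifiers are opaque text so
leading-zero commune codes survive round trips. Rasters are single-band
ESRI ASCII grids (`.asc`) with a `.prj` sidecar naming the reference
system; the format is plain text, diff-able, and sufficient for
single-band temperature and class-code layers. Tables are UTF-8 CSV
with a header row and dot decimal separator.

## Known limitations

* Equal weighting is an assumption, not an estimate; data-driven
  weighting would require outcome data at commune resolution.
* The AC rate is the only protective indicator; vegetation enters only
  through its complement in the exposure fraction.
* Pixel-centre zonal statistics under-sample units much smaller than a
  pixel; the resolution check in the generator guards the synthetic
  case, and real inputs should keep pixels well below the unit scale.
* No uncertainty is propagated to the final classes; a unit near a
  quantile break can change class under small input perturbations.
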