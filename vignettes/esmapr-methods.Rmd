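---
title: "Methods: land-cover change accounts and matrix-based ES assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-cover change accounts and matrix-based ES assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmapr)
```

## The model

`esmapr` is a tier-1 ecosystem-service (ES) assessment engine: it takes a
series of annual categorical land-cover rasters as the sole biophysical
input and derives (i) ecosystem-extent change accounts and (ii) maps and
zonal summaries of *potential* ES supply. "Tier 1" means the land-cover
class is the unit of analysis — no ecosystem-condition, climate or
management covariates enter. This is the standard compromise in data-scarce
national assessments: coarse, but consistent, transparent, and computable
from open global products.

Three assumptions follow directly and bound what the outputs mean:

1. **Class homogeneity.** Every pixel of a class supplies every service at
   the same rate, everywhere, in every year. Within-class condition
   gradients are invisible.
2. **Potential, not actual supply.** Scores encode capacity; use, demand,
   and access are out of scope.
3. **Map truth.** The land-cover product is taken at face value. Transitions
   between classes with small net change are the first casualty of
   classification error, which is why accounts are computed over the full
   yearly series rather than only endpoint-to-endpoint.

## Change accounts

For years $a < b$ on a shared grid, the transition matrix is
$T_{rc} = \sum_{p \,:\, L_a(p)=r,\ L_b(p)=c} A(p)$, with $A(p)$ the pixel
area in km². Row sums are year-$a$ class areas, column sums year-$b$ areas,
and net change per class is $\Delta_c = \sum_r T_{rc} - \sum_c T_{cr}$, which
sums to zero by construction (area conservation — asserted to 1e-6 relative
in the test suite). Percent change vs the baseline year is
$100\,\Delta/A_{base}$, reported as `NA` when the baseline area is zero
(an infinity helps nobody in a table).

Pixels that are nodata in *either* year of a pair are excluded from that
pair's matrix and their area reported separately: the accounts deliberately
have no "to/from nodata" class, because with a fixed national mask such
flows are artifacts.

**Pixel areas.** Two modes, chosen per grid. `nominal`: a constant per-pixel
area (0.01 km² for 100 m cells) for projected grids, and the mode all
synthetic tests use, so oracle comparisons are exact. `geodesic`: for
north-up geographic grids, the spherical-zone closed form
$A = R^2\,|\Delta\lambda|\,|\sin\varphi_{top}-\sin\varphi_{bot}|$ with
$R = 6371.0072$ km; over a study area spanning several degrees of latitude
the cos-latitude weighting shifts zonal areas by a few percent, which is why
geodesic is the default on geographic CRSs. Whether published area tables
used constant or geodesic pixel areas is generally unstated; both modes are
first-class so a reproduction can report both.

**Zone assignment** uses the pixel-center point (even-odd rule, edge points
inside). It is deterministic, matches the common zonal-statistics
convention, and makes zonal accounts exactly additive when zones tile the
area — the hierarchy invariants (national = Σ regional = Σ sub-regional,
1e-6 relative) are tested, not assumed.

## The ES matrix

Scores live on the 0–5 Likert scale. The consensus construction is: collect
per-study score tables, crosswalk each onto the target legend and service
registry, then per (service, class) take the minimum, arithmetic mean and
maximum over the studies *reporting that pair*, recording `n_studies`.

Two decisions here were genuinely open:

- **Missing ≠ zero.** A (service, class) cell no study covers is marked
  missing and propagates nodata through scoring and aggregation. 0 is a
  meaningful score ("no potential"); conflating the two would silently bias
  consensus means downward. This also resolves the ambiguity of whether the
  average is over reporting studies or over all studies with absent = 0:
  `esmapr` averages over reporting studies only.
- **Crosswalk merging.** When several source classes (or services) collapse
  onto one target, the merged score is the arithmetic mean of the source
  scores — the least-biased default when nothing is known about the source
  classes' relative extents. (Taking the max instead would make the min/avg
  variants inconsistent; a max-biased reading is already available via the
  max variant itself.)

The package ships `synthetic_es_matrix()`, a hand-set, clearly-labelled
*synthetic* score table following the field's canonical pattern (forest and
wetland classes high for regulating and cultural services, cropland dominant
for crop provisioning, bare/built-up low). It exists so the pipeline runs
out of the box; no correctness test depends on its values, and any real
assessment must substitute a transcribed literature matrix.

## Aggregation and standardization

The overall-supply surface per (variant, year) is the unweighted per-pixel
sum over the ten services — "equal weights" is a policy statement, not a
statistical one — over pixels valid in *all* services. Standardization is
min–max over valid pixels to [0, 1] (the display convention of published
overall maps); an all-constant raw map maps to all zeros, the only stable
degenerate choice. Division by the theoretical maximum $5K$ is available
(`standardize = "theoretical"`) when cross-year comparability of the
standardized surface matters more than full dynamic range: min–max
standardized maps of different years are *not* directly comparable because
their anchors differ.

Zonal summaries report the area-weighted mean per unit area (score units,
0–5 for single services) and total potential (score·km²). The per-zone
`OVERALL` value is the unweighted mean of the ten per-service means — the
reading most consistent with equal service weights; the zonal mean of the
raw aggregate surface is available via `overall = "aggregate_raster"`.
Report rounding (means and changes to 2 decimals, totals to whole units) is
applied only at presentation time; every computation and every tidy CSV from
the change command keeps full precision, so cross-file invariants survive
round-tripping.

## The synthetic world

The generator is a stated world, not a tuning knob; its defaults are fixed
as follows.

- **Mosaic**: `n_patches` points drawn uniformly; each patch gets a class
  sampled from the configured proportions; pixels take their nearest seed's
  class (Voronoi). Default proportions mirror an arid national landscape:
  50.0% bare/sparse (60), 26.5% shrubs (20), 17.2% herbaceous (30), 5.6%
  cropland (40), with the remaining 0.7% split among built-up, water,
  wetland and four forest classes. Default grid: 500×500 pixels at 100 m
  (nominal 0.01 km²), projected CRS; 2,000 patches, giving a mean patch of
  ~125 px — coarse enough for real spatial autocorrelation, fine enough
  that realized shares track the target within binomial error over patches.
- **Change**: pixel-independent Markov transitions. The default matrix moves
  bare → herbaceous at 1.9%/yr (≈7.5% of the bare class over four steps —
  the magnitude of a strong national greening signal), with minor flows to
  wetland and water and a small shrubs → herbaceous term; everything else
  persists. Independence is unrealistic (real change is spatially clumped)
  but gives an analytically known ground truth: the row-normalized empirical
  transition matrix is a binomial estimator of P, and the recovery test
  checks every cell within 3 standard errors.
- **Zones**: rectangular tiling, 6 regions × 10 sub-regions by default
  (standing in for a six-region / 57-sub-region hierarchy), plus a national
  zone. Split lines snap to pixel edges so no boundary passes through a
  pixel center — zones tile the pixels exactly and hierarchical additivity
  is exact rather than approximate.
- **Studies**: a latent integer score per (service, class), perturbed per
  study by rounded Gaussian noise (sd 0.8 score units — studies mostly
  agree within one Likert step), clipped to [0, 5]; optional partial
  coverage. The exact consensus of the realized studies is computed at
  generation time by direct array reduction, independently of
  `build_consensus_matrix()`, so the two routes check each other.

What a green test on this world does **not** establish: robustness to
classification noise (not modeled), to spatially correlated change, to
non-rectangular or overlapping admin geometries, or to the reprojection /
resampling steps that real tiles need before entering the pipeline (the
package requires inputs on one grid and does not resample).

## Numerical and format choices

- Grid equality uses 1e-9 relative tolerance on the transform (file metadata
  is floating point); dimensions and CRS must match exactly.
- Integer rasters round-trip bit-exactly through the ASCII-grid writer;
  score rasters are written at full `%.17g` precision. ESRI ASCII grid and
  GeoJSON replace GeoTIFF/GeoPackage because the target environment has no
  GDAL bindings; both are lossless for the data carried here (square-cell,
  north-up grids; polygonal zones).
- Values outside the legend are remapped to nodata with a warned count
  rather than raising: real global tiles legitimately contain classes absent
  from one country.
- Service ranking breaks ties by service code ascending, making reports
  deterministic.
- All generators restore the caller's RNG state and expand one global seed
  into fixed per-component offsets, so any component can be regenerated
  independently and reruns are byte-identical.

## Limitations

Beyond the tier-1 assumptions above: no accuracy/uncertainty propagation
from the land-cover product; no trade-off or synergy analysis between
services; no economic valuation; five annual time steps are too short for
trend inference — the change accounts describe, they do not extrapolate.
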