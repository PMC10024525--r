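# esmapr

National mapping and assessment of ecosystem services (ES) from annual
land-cover maps.

`esmapr` implements a tier-1 MAES / SEEA-EA-style workflow for analysts who
need country-scale answers from categorical land-cover products alone: how
have ecosystems changed year over year, and what does that imply for the
potential supply of key ecosystem services? It was designed around the data
situation of arid East-African countries (100 m Copernicus-style annual land
cover, nested admin boundaries, no field data), but nothing in it is specific
to one country.

## What it computes

**Land-cover change accounts.** For a series of annual categorical rasters on
one grid: per-class area tables; K×K *transition matrices*
`T[r, c] = area(class r in year a AND class c in year b)` (diagonal =
persistence, column sum − row sum = net change); and net/percent change
relative to a baseline year — nationally and per administrative zone at two
nested levels.

**ES-matrix scoring.** The matrix approach assigns each land-cover class `k` a
potential-supply score `s(e, k) ∈ [0, 5]` per service `e`, so mapping a
service reduces to reclassifying the land-cover raster through the score
table. The shipped machinery builds that table as a *consensus* over
literature studies — per cell the min / arithmetic mean / max across the
studies that report it (cells no study covers are *missing*, not 0) — after
crosswalking each study's class and service nomenclature onto the target
legend (merged source cells average).

**Equal-weight aggregation and zonal statistics.** Per (variant, year) the
per-service rasters are summed with equal weights and min–max standardized to
[0, 1] (a pixel must be valid in *every* service). Every surface is summarized
per zone as the area-weighted mean per unit area
`Σ(s·A_px)/Σ(A_px)` and the total potential `Σ(s·A_px)` (score·km²), with
changes vs the baseline year and per-zone service rankings. Pixel areas are
either nominal (constant, projected grids) or geodesic
(`A = R²·|Δλ|·|sin φ_top − sin φ_bottom|`, R = 6371.0072 km) for geographic
grids.

**Synthetic landscapes with known truth.** A generator produces
CGLC-like 11-class Voronoi patch mosaics with stated class proportions,
evolves them with a known row-stochastic Markov transition matrix (default: a
"greening" flow, bare/sparse → herbaceous at 1.9 %/yr), tiles nested
rectangular admin zones, and fabricates literature study sets whose exact
consensus is returned alongside — so every stage of the pipeline is testable
offline against ground truth.

All artifacts are plain text: rasters as ESRI ASCII grids (`.asc`, with a
`.crs` sidecar), zones as GeoJSON, tables as CSV, configs as YAML.

## Worked example

```r
library(esmapr)

# a 200 x 200 synthetic landscape (100 m pixels), evolved 2015 -> 2019
cfg    <- landscape_config(es_grid(200, 200, 100, -100, 0, 20000),
                           n_patches = 600, seed = 42)
series <- generate_series(cfg, years = c(2015, 2019))
ar     <- pixel_areas(cfg$grid, "nominal", nominal_area_km2 = 0.01)

round(net_change(transition_matrix(series[[1]], series[[2]], ar)), 1)
#>   20   30   40   50   60   80   90  114  116  124  126
#> -0.2  4.0  0.0  0.0 -3.9  0.1  0.1  0.0  0.0  0.0  0.0
```

Herbaceous vegetation (class 30) gains ~4 km² while bare/sparse (60) loses
~3.9 km² — the generator's greening flow, recovered from the maps by the
change account (net changes always sum to 0: area is conserved).

```r
zones <- generate_zones(cfg$grid, n_regions = 6, subs_per_region = 10)
mat   <- synthetic_es_matrix()        # clearly-labelled synthetic score table
stack <- score_stack(series, mat, variants = "max", years = c(2015, 2019))
ch    <- summarize_changes(summarize_stack(stack, zones, ar), 2015)
subset(ch, level == "national" & year == 2019,
       c(service_code, mean_per_unit_area, change_vs_baseline))
#>  service_code mean_per_unit_area change_vs_baseline
#>       OVERALL               1.33              0.016
#>             a               0.69              0.009
#>             b               2.26              0.038
#>             c               0.60             -0.001
#>             ...
rank_services(summarize_stack(stack, zones, ar), "NAT", 2019, "max")
#> [1] "b" "j" "h" "i" "g" "f" "e" "a" "c" "d"
```

`mean_per_unit_area` is the national mean potential-supply score (0–5) per
service for 2019; `change_vs_baseline` its change since 2015. Services whose
score for herbaceous exceeds their score for bare gain (grazed biomass `b`
most, +0.04); wood supply `c` is flat-to-negative, as conversion to grassland
does not add trees. The `OVERALL` row is the unweighted mean of the ten
per-service means.

## Command line

```sh
exec/esmap simulate --scenario scenario.yaml --out sim/
exec/esmap change   --rasters "sim/lc_*.asc" --baseline 2015 \
                    --zones sim/zones.geojson --out change/
exec/esmap score    --rasters "sim/lc_*.asc" --matrix sim/es_matrix_synthetic.csv \
                    --variants avg,max --zones sim/zones.geojson --out score/
exec/esmap report   --summary score/
```

Exit codes: 1 usage, 2 data validation, 3 internal. Reruns with the same
config are byte-identical.

## Reproducing a real national assessment

The package ships no downloader. To run it on real data: fetch the annual
Copernicus Global Land Cover v3.0 discrete-classification tiles covering your
country (100 m, years 2015–2019), convert to ASCII grid on a single common
grid, clip with your national boundary (`clip_to_boundary()`), supply the
admin zones as GeoJSON with `zone_id,name,level,parent_id` properties, and
transcribe a literature score matrix into the long CSV format (see
`write_es_matrix()`). Use `--area-mode geodesic` for geographic grids; the
change accounts report both nominal and geodesic areas identically up to the
cos-latitude weighting. The shipped `synthetic_es_matrix()` is a stand-in for
development only.
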