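Package: esmapr
Title: National Mapping and Assessment of Ecosystem Services from Land Cover
Version: 0.1.0
Authors@R: person("Maintainer", "esmapr", email = "esmapr@example.org",
    role = c("aut", "cre"))
Description: A tier-1 pipeline for mapping and assessing potential ecosystem
    service (ES) supply from annual categorical land-cover rasters, in the
    style of national MAES / SEEA-EA extent accounting. Computes per-class
    area accounts, year-to-year land-cover transition matrices and
    percent-change tables relative to a baseline year; scores land cover into
    per-service potential-supply rasters with a literature-consensus ES matrix
    (min/avg/max variants on a 0-5 scale); aggregates services with equal
    weights into standardized overall-supply maps; and summarizes everything
    as area-weighted zonal statistics over nested administrative zones. A
    synthetic-landscape generator (Voronoi patch mosaics evolved by a Markov
    class-transition model, nested rectangular admin zones, literature-style
    study score matrices with known ground truth) makes the whole pipeline
    testable without any external download. Rasters are exchanged as ESRI
    ASCII grids and zones as GeoJSON, so every artifact is plain text.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
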