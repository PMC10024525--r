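# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive per-pixel double loops, sharing no code with the
# package's vectorized paths.

toy_legend <- function() {
  es_legend(c(20L, 30L, 40L, 60L),
            c("Shrubs", "Herbaceous", "Cultivated", "Bare"), nodata = 0L)
}

toy_grid <- function(nr = 2, nc = 2, cell = 100) {
  es_grid(nr, nc, pixel_width = cell, pixel_height = -cell,
          origin_x = 0, origin_y = nr * cell, crs = "local")
}

toy_lc <- function(vals, year = 2015, legend = toy_legend(), cell = 100) {
  vals <- as.matrix(vals)
  es_landcover(vals, toy_grid(nrow(vals), ncol(vals), cell), year, legend)
}

unit_areas <- function(grid) pixel_areas(grid, "nominal", nominal_area_km2 = 1)

# random categorical raster (codes from the toy legend + optional nodata)
rand_lc <- function(nr, nc, year = 2015, p_nodata = 0.1,
                    legend = toy_legend()) {
  codes <- c(legend$class_code, rep(attr(legend, "nodata"),
                                    round(p_nodata * 10)))
  vals <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  es_landcover(vals, toy_grid(nr, nc), year, legend)
}

# ---- oracles -----------------------------------------------------------

bf_class_areas <- function(lc, areas) {
  nd <- attr(lc$legend, "nodata")
  acc <- setNames(numeric(nrow(lc$legend)), lc$legend$class_code)
  for (i in seq_len(nrow(lc$values))) for (j in seq_len(ncol(lc$values))) {
    v <- lc$values[i, j]
    if (v != nd) acc[as.character(v)] <- acc[as.character(v)] +
        areas$per_row_area_km2[i]
  }
  acc
}

bf_transition <- function(lc_a, lc_b, areas) {
  nd <- attr(lc_a$legend, "nodata")
  codes <- as.character(lc_a$legend$class_code)
  m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
  for (i in seq_len(nrow(lc_a$values))) for (j in seq_len(ncol(lc_a$values))) {
    a <- lc_a$values[i, j]; b <- lc_b$values[i, j]
    if (a != nd && b != nd)
      m[as.character(a), as.character(b)] <-
        m[as.character(a), as.character(b)] + areas$per_row_area_km2[i]
  }
  m
}

# zonal mean/total oracle for rectangular zones: pixel-center-in-bbox
# assignment, independent of sp and of zone_index()
bf_zonal <- function(values, grid, areas, rects) {
  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_width
  ys <- grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$pixel_height
  out <- list()
  for (z in names(rects)) {
    r <- rects[[z]]
    tot <- 0; wsum <- 0
    for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
      if (xs[j] >= r[1] && xs[j] <= r[3] && ys[i] >= r[2] && ys[i] <= r[4] &&
          !is.na(values[i, j])) {
        tot <- tot + values[i, j] * areas$per_row_area_km2[i]
        wsum <- wsum + areas$per_row_area_km2[i]
      }
    }
    out[[z]] <- c(mean = if (wsum > 0) tot / wsum else NA_real_, total = tot)
  }
  out
}

# rectangle bounds of each zone of a generated (rectangular) zone set
zone_rects <- function(zones, level) {
  zs <- zones[zones$level == level, ]
  rects <- lapply(zs$geometry, function(g) {
    ring <- g$polys[[1]][[1]]
    c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]), max(ring[, 2]))
  })
  names(rects) <- zs$zone_id
  rects
}

# write a raw ASCII grid by hand (for read-path tests)
write_raw_asc <- function(path, rows, cellsize = 100, nodata = 0) {
  nr <- length(rows)
  nc <- length(strsplit(trimws(rows[1]), " ")[[1]])
  writeLines(c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %g", cellsize),
               sprintf("NODATA_value %g", nodata), rows), path)
  path
}
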