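.datatable.aware <- TRUE

# Shared helper: data.table of valid pixels with class code and area weight.
pixel_table <- function(lc, areas) {
  w <- area_weights(areas, lc$grid)
  nd <- legend_nodata(lc$legend)
  keep <- lc$values != nd
  data.table::data.table(code = as.vector(lc$values[keep]),
                         w = as.vector(w[keep]),
                         cell = which(keep))
}

#' Per-class area account
#'
#' Sums pixel areas by land-cover class, nationally and (when a zone set is
#' given) per administrative zone at every level present. Nodata pixels are
#' excluded. All legend classes appear in the output, zero-filled where
#' absent, so yearly tables always conform.
#'
#' @param lc an `es_landcover`.
#' @param areas an `es_pixel_areas` for the raster's grid.
#' @param zones optional `es_zoneset`; when `NULL` a single national account
#'   with `zone_id = "ALL"` is returned.
#' @return A data.frame with columns `zone_id`, `level`, `year`,
#'   `class_code`, `area_km2`.
#' @export
class_areas <- function(lc, areas, zones = NULL) {
  px <- pixel_table(lc, areas)
  out <- list()
  if (is.null(zones)) {
    agg <- px[, .(area_km2 = sum(w)), by = .(class_code = code)]
    agg[, `:=`(zone_id = "ALL", level = "national")]
    out[["ALL"]] <- agg
  } else {
    for (lv in intersect(c("national", "regional", "sub_regional"),
                         unique(zones$level))) {
      zidx <- zone_index(zones, lc$grid, lv)
      zs <- zones_at_level(zones, lv)
      z <- as.vector(zidx)[px$cell]
      sub <- px[!is.na(z)]
      sub[, zone := zs$zone_id[z[!is.na(z)]]]
      agg <- sub[, .(area_km2 = sum(w)), by = .(zone_id = zone,
                                                class_code = code)]
      agg[, level := lv]
      out[[lv]] <- agg
    }
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  # zero-fill missing classes per zone
  full <- data.table::CJ(zone_id = unique(res$zone_id),
                         class_code = legend_codes(lc$legend))
  res <- merge(full, res, by = c("zone_id", "class_code"), all.x = TRUE)
  res[, level := level[!is.na(level)][1], by = zone_id]
  res[is.na(area_km2), area_km2 := 0]
  res[, year := lc$year]
  data.table::setcolorder(res, c("zone_id", "level", "year", "class_code",
                                 "area_km2"))
  data.table::setorder(res, level, zone_id, class_code)
  as.data.frame(res)
}

#' Land-cover transition matrix between two years
#'
#' Cell (r, c) holds the total area (km2) of pixels mapped as class r in the
#' earlier year and class c in the later year; the diagonal is persistence.
#' Pixels that are nodata in either year are excluded from the matrix and
#' their area reported in the `excluded_km2` field (class-to/from-nodata is
#' not an account entry). Row sums equal earlier-year class areas, column
#' sums later-year class areas, over the common valid mask.
#'
#' @param lc_a,lc_b `es_landcover` rasters sharing grid and legend, with
#'   `lc_a$year < lc_b$year`.
#' @param areas an `es_pixel_areas`.
#' @param zone optional `es_geom`; when given, only pixels whose centers fall
#'   inside it contribute.
#' @param zone_id label recorded on the result.
#' @return An object of class `es_transition` with fields `cells` (K x K
#'   matrix, dimnames = class codes), `year_from`, `year_to`, `legend`,
#'   `zone_id`, `excluded_km2`.
#' @export
transition_matrix <- function(lc_a, lc_b, areas, zone = NULL,
                              zone_id = "ALL") {
  if (!grid_equal(lc_a$grid, lc_b$grid))
    abort(sprintf("grids differ (field '%s')",
                  grid_diff_field(lc_a$grid, lc_b$grid)), "alignment")
  if (!legend_equal(lc_a$legend, lc_b$legend))
    abort("legends differ between the two rasters", "alignment")
  if (lc_a$year >= lc_b$year)
    abort("lc_a must be the earlier year", "contract")
  codes <- legend_codes(lc_a$legend)
  nd <- legend_nodata(lc_a$legend)
  K <- length(codes)
  w <- area_weights(areas, lc_a$grid)
  mask <- lc_a$values != nd & lc_b$values != nd
  if (!is.null(zone)) {
    grid <- lc_a$grid
    pts <- expand.grid(y = row_centers_y(grid), x = col_centers_x(grid))
    inside <- matrix(points_in_geom(pts$x, pts$y, zone),
                     grid$n_rows, grid$n_cols)
    excluded <- sum(w[inside & !mask])
    mask <- mask & inside
  } else {
    excluded <- sum(w[!mask])
  }
  i <- match(lc_a$values[mask], codes)
  j <- match(lc_b$values[mask], codes)
  cells <- matrix(0, K, K, dimnames = list(from = codes, to = codes))
  if (any(mask)) {
    acc <- rowsum(w[mask], group = (j - 1L) * K + i)
    cells[as.integer(rownames(acc))] <- acc[, 1]
  }
  structure(list(cells = cells, year_from = lc_a$year, year_to = lc_b$year,
                 legend = lc_a$legend, zone_id = zone_id,
                 excluded_km2 = excluded),
            class = "es_transition")
}

#' @export
print.es_transition <- function(x, ...) {
  cat(sprintf("<es_transition> %d -> %d, zone %s, total %.6g km2 (%.6g excluded)\n",
              x$year_from, x$year_to, x$zone_id, sum(x$cells), x$excluded_km2))
  print(round(x$cells, 2))
  invisible(x)
}

#' Net area change per class
#'
#' Column sum minus row sum of a transition matrix: the signed area gained
#' (+) or lost (-) by each class over the period. Conservation holds by
#' construction: the net changes sum to zero.
#'
#' @param tm an `es_transition`.
#' @return Named numeric vector (names = class codes), in km2.
#' @export
net_change <- function(tm) {
  colSums(tm$cells) - rowSums(tm$cells)
}

#' Net and percent change relative to a baseline year
#'
#' For every zone, class and year: `net_change_km2 = area(year) -
#' area(baseline)` and `percent_change = 100 * net / area(baseline)`
#' (`NA` when the baseline area is zero, rather than an infinity).
#'
#' @param series list of `es_landcover` (validated and sorted internally).
#' @param baseline_year the reference year; must be in the series.
#' @param areas an `es_pixel_areas`.
#' @param zones optional `es_zoneset`.
#' @return A data.frame with columns `zone_id`, `level`, `class_code`,
#'   `year`, `area_km2`, `net_change_km2`, `percent_change`.
#' @export
change_table <- function(series, baseline_year, areas, zones = NULL) {
  series <- validate_series(series)
  years <- vapply(series, function(r) r$year, integer(1))
  if (!baseline_year %in% years)
    abort(sprintf("baseline year %d not in series (%s)", baseline_year,
                  paste(years, collapse = ", ")), "contract")
  at <- data.table::rbindlist(
    lapply(series, function(lc) class_areas(lc, areas, zones)))
  base <- at[year == baseline_year,
             .(zone_id, class_code, base_area = area_km2)]
  out <- merge(at, base, by = c("zone_id", "class_code"))
  out[, net_change_km2 := area_km2 - base_area]
  out[, percent_change := ifelse(base_area == 0, NA_real_,
                                 100 * net_change_km2 / base_area)]
  out[, base_area := NULL]
  data.table::setcolorder(out, c("zone_id", "level", "class_code", "year",
                                 "area_km2", "net_change_km2",
                                 "percent_change"))
  data.table::setorder(out, level, zone_id, class_code, year)
  as.data.frame(out)
}
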