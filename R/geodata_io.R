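#' Mask a land-cover raster to a boundary
#'
#' Pixels whose centers fall outside the boundary polygon become nodata; the
#' grid is left untouched (no cropping), so all yearly rasters of a series
#' stay aligned by construction. Pixel-to-boundary assignment uses the pixel
#' center point, the usual zonal-statistics convention.
#'
#' @param lc an `es_landcover`.
#' @param boundary an `es_geom` in the same CRS as the raster.
#' @return An `es_landcover` with exterior pixels set to nodata.
#' @export
clip_to_boundary <- function(lc, boundary) {
  if (boundary$crs != lc$grid$crs)
    abort(sprintf("boundary CRS (%s) differs from raster CRS (%s)",
                  boundary$crs, lc$grid$crs), "contract")
  grid <- lc$grid
  xs <- col_centers_x(grid); ys <- row_centers_y(grid)
  pts <- expand.grid(y = ys, x = xs)   # column-major, matches matrix layout
  inside <- points_in_geom(pts$x, pts$y, boundary)
  vals <- lc$values
  vals[!inside] <- legend_nodata(lc$legend)
  es_landcover(vals, grid, lc$year, lc$legend)
}

#' Validate a multi-year land-cover series
#'
#' Confirms that all rasters share one grid and one legend and that years are
#' distinct, then returns the series sorted by year. A grid mismatch raises an
#' alignment error naming the first differing grid field.
#'
#' @param rasters list of `es_landcover` (at least 2).
#' @return The list sorted by year.
#' @export
validate_series <- function(rasters) {
  if (length(rasters) < 2)
    abort("a series needs at least two yearly rasters", "contract")
  years <- vapply(rasters, function(r) r$year, integer(1))
  if (anyDuplicated(years))
    abort(sprintf("duplicate year(s) in series: %s",
                  paste(years[duplicated(years)], collapse = ", ")),
          "contract")
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!grid_equal(ref$grid, r$grid))
      abort(sprintf("grids differ between years %d and %d (field '%s')",
                    ref$year, r$year, grid_diff_field(ref$grid, r$grid)),
            "alignment")
    if (!legend_equal(ref$legend, r$legend))
      abort(sprintf("legends differ between years %d and %d", ref$year, r$year),
            "alignment")
  }
  rasters[order(years)]
}
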