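#' Raster grid geometry
#'
#' A grid records the georeferencing shared by every raster in a series: CRS
#' identifier, the outer corner of pixel (1,1) (the "origin", conventionally
#' the top-left corner for north-up rasters), signed pixel sizes in CRS units,
#' and the raster dimensions. `pixel_height` is negative for north-up grids
#' (row index increases southward).
#'
#' @param n_rows,n_cols positive integer raster dimensions.
#' @param origin_x,origin_y coordinates of the outer corner of the first
#'   pixel (top-left for north-up grids).
#' @param pixel_width,pixel_height signed cell sizes in CRS units; non-zero.
#'   `pixel_height` should be negative for north-up grids.
#' @param crs coordinate reference system identifier. `"EPSG:4326"` (or any
#'   string containing `4326`, `longlat` or `WGS84`) marks the grid as
#'   geographic, which enables geodesic pixel areas; anything else is treated
#'   as projected.
#' @return An object of class `es_grid`.
#' @export
es_grid <- function(n_rows, n_cols, pixel_width, pixel_height,
                    origin_x = 0, origin_y = 0, crs = "local") {
  if (n_rows < 1 || n_cols < 1)
    abort("grid dimensions must be >= 1", "contract")
  if (pixel_width == 0 || pixel_height == 0)
    abort("pixel sizes must be non-zero", "contract")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_width = pixel_width, pixel_height = pixel_height,
         origin_x = origin_x, origin_y = origin_y, crs = as.character(crs)),
    class = "es_grid")
}

#' @export
print.es_grid <- function(x, ...) {
  cat(sprintf("<es_grid> %d x %d pixels, cell %g x %g, origin (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$pixel_width, x$pixel_height,
              x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

is_geographic <- function(grid) {
  grepl("4326|longlat|wgs ?84|geographic", grid$crs, ignore.case = TRUE)
}

#' Compare two grids for equality
#'
#' Numeric fields are compared within a relative tolerance of 1e-9 (grid
#' transforms come from file metadata and carry floating-point noise); the CRS
#' id and dimensions must match exactly.
#'
#' @param a,b `es_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grid_equal <- function(a, b) {
  if (a$n_rows != b$n_rows || a$n_cols != b$n_cols) return(FALSE)
  if (a$crs != b$crs) return(FALSE)
  num <- c("pixel_width", "pixel_height", "origin_x", "origin_y")
  all(vapply(num, function(f) rel_close(a[[f]], b[[f]]), logical(1)))
}

# Name of the grid field that differs, for alignment error messages.
grid_diff_field <- function(a, b) {
  for (f in c("n_rows", "n_cols", "crs",
              "pixel_width", "pixel_height", "origin_x", "origin_y")) {
    va <- a[[f]]; vb <- b[[f]]
    same <- if (is.numeric(va)) rel_close(va, vb) else identical(va, vb)
    if (!same) return(f)
  }
  NULL
}

# Pixel-center coordinates. Columns map to x, rows to y.
col_centers_x <- function(grid) {
  grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_width
}
row_centers_y <- function(grid) {
  grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$pixel_height
}

#' Per-pixel areas for a grid
#'
#' Two modes. `"nominal"`: every pixel has the same stated area (use for
#' projected grids, e.g. 0.01 km2 for a 100 m cell). `"geodesic"`: for
#' north-up geographic grids, the spherical-zone formula per row,
#' `A(row) = R^2 |dlambda| |sin(phi_top) - sin(phi_bottom)|` with the
#' authalic-like radius R = 6371.0072 km, so area falls off with the cosine of
#' latitude.
#'
#' @param grid an `es_grid`.
#' @param mode `"nominal"` or `"geodesic"`.
#' @param nominal_area_km2 constant pixel area, used in nominal mode.
#' @return An object of class `es_pixel_areas` with fields `mode`,
#'   `nominal_area_km2` and `per_row_area_km2` (length `n_rows`).
#' @export
pixel_areas <- function(grid, mode = c("nominal", "geodesic"),
                        nominal_area_km2 = NULL) {
  mode <- match.arg(mode)
  if (mode == "nominal") {
    if (is.null(nominal_area_km2) || nominal_area_km2 <= 0)
      abort("nominal mode needs a positive nominal_area_km2", "contract")
    per_row <- rep(nominal_area_km2, grid$n_rows)
  } else {
    if (!is_geographic(grid))
      abort("geodesic pixel areas require a geographic CRS", "contract")
    R <- 6371.0072
    top <- grid$origin_y + (seq_len(grid$n_rows) - 1) * grid$pixel_height
    bot <- top + grid$pixel_height
    per_row <- R^2 * abs(grid$pixel_width * pi / 180) *
      abs(sin(top * pi / 180) - sin(bot * pi / 180))
    nominal_area_km2 <- NA_real_
  }
  if (any(per_row <= 0)) abort("pixel areas must be strictly positive", "contract")
  structure(list(mode = mode, nominal_area_km2 = nominal_area_km2,
                 per_row_area_km2 = per_row, n_rows = grid$n_rows),
            class = "es_pixel_areas")
}

# Area of the pixel in each row, recycled across columns: returns an
# n_rows x n_cols matrix-conformable weight vector (by column-major matrix
# layout, rep the per-row vector n_cols times).
area_weights <- function(areas, grid) {
  if (areas$n_rows != grid$n_rows)
    abort("pixel-area field does not match grid rows", "alignment")
  matrix(rep(areas$per_row_area_km2, grid$n_cols),
         nrow = grid$n_rows, ncol = grid$n_cols)
}
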