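#' Land-cover raster
#'
#' A single-year categorical raster: an integer matrix of class codes (row 1
#' is the top row), the grid it sits on, its year, and its legend. Any value
#' that is neither a legend code nor the nodata code violates the container's
#' invariant; constructors remap such values (see [read_landcover()]).
#'
#' @param values integer matrix, `n_rows x n_cols`.
#' @param grid an `es_grid` matching the matrix dimensions.
#' @param year integer observation year.
#' @param legend an `es_legend`.
#' @return An object of class `es_landcover`.
#' @export
es_landcover <- function(values, grid, year, legend) {
  if (!is.matrix(values) ||
      nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    abort("values matrix does not match grid dimensions", "contract")
  storage.mode(values) <- "integer"
  bad <- !(values %in% c(legend_codes(legend), legend_nodata(legend)))
  if (any(bad))
    abort(sprintf("%d raster values are outside the legend", sum(bad)),
          "validation")
  structure(list(values = values, grid = grid, year = as.integer(year),
                 legend = legend),
            class = "es_landcover")
}

#' @export
print.es_landcover <- function(x, ...) {
  nd <- sum(x$values == legend_nodata(x$legend))
  cat(sprintf("<es_landcover> year %d, %d x %d, %d classes, %d nodata pixels\n",
              x$year, x$grid$n_rows, x$grid$n_cols,
              nrow(x$legend), nd))
  invisible(x)
}

#' Continuous score raster
#'
#' Floating-point raster of potential ES supply scores (or of raw/standardized
#' aggregates). `NA` is the nodata sentinel. Carries the service code, the
#' score variant and the year it was derived from.
#'
#' @param values numeric matrix; `NA` = nodata.
#' @param grid an `es_grid`.
#' @param service service code (one letter, or `"OVERALL"`).
#' @param variant `"min"`, `"avg"` or `"max"`.
#' @param year integer year.
#' @return An object of class `es_score_raster`.
#' @export
es_score_raster <- function(values, grid, service, variant, year) {
  if (!is.matrix(values) ||
      nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    abort("values matrix does not match grid dimensions", "contract")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, service = service,
                 variant = variant, year = as.integer(year)),
            class = "es_score_raster")
}

# ---- ESRI ASCII grid IO ------------------------------------------------
# Plain-text raster interchange. Square cells and north-up orientation only
# (the format has a single `cellsize`). CRS is carried in an optional
# "<path>.crs" sidecar, defaulting to "local".

asc_header <- function(grid, nodata) {
  if (!rel_close(abs(grid$pixel_width), abs(grid$pixel_height)))
    abort("ASCII grid requires square cells", "contract")
  if (grid$pixel_height >= 0)
    abort("ASCII grid writer requires a north-up grid (pixel_height < 0)",
          "contract")
  yll <- grid$origin_y + grid$n_rows * grid$pixel_height
  sprintf(paste0("ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\n",
                 "cellsize %.17g\nNODATA_value %s"),
          grid$n_cols, grid$n_rows, grid$origin_x, yll,
          abs(grid$pixel_width), format(nodata))
}

write_asc <- function(values, grid, path, nodata, fmt) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(asc_header(grid, nodata), con)
  vals <- values
  vals[is.na(vals)] <- nodata
  lines <- apply(vals, 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  writeLines(lines, con)
  crs_path <- paste0(path, ".crs")
  writeLines(grid$crs, crs_path)
  invisible(path)
}

read_asc <- function(path) {
  if (!file.exists(path)) abort(paste("raster file not found:", path), "io")
  lines <- readLines(path)
  if (length(lines) < 7) abort(paste("not an ASCII grid:", path), "io")
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    abort(paste("malformed ASCII grid header in", path), "io")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(text = lines[-(1:6)], what = double(), quiet = TRUE)
  if (length(body) != nr * nc)
    abort(sprintf("expected %d cells, found %d in %s",
                  nr * nc, length(body), path), "io")
  crs_path <- paste0(path, ".crs")
  crs <- if (file.exists(crs_path)) readLines(crs_path, n = 1) else "local"
  grid <- es_grid(nr, nc, pixel_width = hdr$cellsize,
                  pixel_height = -hdr$cellsize,
                  origin_x = hdr$xllcorner,
                  origin_y = hdr$yllcorner + nr * hdr$cellsize,
                  crs = crs)
  values <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  list(values = values, grid = grid, nodata = hdr$nodata_value)
}

#' Read a categorical land-cover raster
#'
#' Reads a single-band integer raster (ESRI ASCII grid). Values that are not
#' in the legend are remapped to the nodata code; the number of remapped cells
#' is reported in a warning (large CGLC tiles routinely contain classes absent
#' from the study area). A floating-point band is refused.
#'
#' @param path path to an `.asc` file. A sidecar `<path>.crs`, if present,
#'   supplies the CRS id.
#' @param year integer year of the map.
#' @param legend an `es_legend`; defaults to [cglc_legend()].
#' @return An `es_landcover`.
#' @export
read_landcover <- function(path, year, legend = cglc_legend()) {
  r <- read_asc(path)
  if (any(r$values != round(r$values), na.rm = TRUE))
    abort(paste("land-cover raster has a floating-point band:", path), "type")
  vals <- matrix(as.integer(r$values), nrow(r$values), ncol(r$values))
  nd <- legend_nodata(legend)
  vals[r$values == r$nodata] <- nd
  out <- !(vals %in% c(legend_codes(legend), nd))
  if (any(out)) {
    warning(sprintf("%d cells with codes outside the legend remapped to nodata (%s)",
                    sum(out),
                    paste(sort(unique(vals[out])), collapse = ", ")),
            call. = FALSE)
    vals[out] <- nd
  }
  es_landcover(vals, r$grid, year, legend)
}

#' Write rasters as ESRI ASCII grids
#'
#' Integer land-cover rasters round-trip bit-exactly through
#' `write_landcover()` / [read_landcover()]. Score rasters are written at full
#' double precision with nodata `-9999`.
#'
#' @param lc an `es_landcover`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_landcover <- function(lc, path) {
  write_asc(lc$values, lc$grid, path, legend_nodata(lc$legend), "%d")
}

#' @rdname write_landcover
#' @param r an `es_score_raster`.
#' @export
write_score_raster <- function(r, path) {
  write_asc(r$values, r$grid, path, -9999, "%.17g")
}

#' @rdname write_landcover
#' @param service,variant,year metadata attached to the score raster on read.
#' @export
read_score_raster <- function(path, service = "", variant = "", year = NA) {
  r <- read_asc(path)
  vals <- r$values
  vals[vals == r$nodata] <- NA_real_
  es_score_raster(vals, r$grid, service, variant,
                  if (is.na(year)) 0L else year)
}
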