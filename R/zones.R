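#' Polygon geometries
#'
#' Minimal multipolygon container used for administrative zones and clipping
#' boundaries: a list of polygons, each polygon a list of rings (first ring
#' exterior, further rings holes), each ring a 2-column matrix of x,y
#' vertices. Point-in-polygon tests follow the even-odd rule via
#' [sp::point.in.polygon()]; points on an edge count as inside.
#'
#' @param polys list of polygons as described above. A single ring matrix or a
#'   single list-of-rings polygon is promoted.
#' @param crs CRS identifier the coordinates are expressed in.
#' @return An object of class `es_geom`.
#' @export
es_geom <- function(polys, crs = "local") {
  if (is.matrix(polys)) polys <- list(list(polys))
  if (is.list(polys) && length(polys) && is.matrix(polys[[1]]))
    polys <- list(polys)
  for (p in polys) for (ring in p) {
    if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3)
      abort("each ring must be a 2-column matrix with >= 3 vertices",
            "contract")
  }
  structure(list(polys = polys, crs = as.character(crs)), class = "es_geom")
}

#' Axis-aligned rectangle geometry
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @param crs CRS identifier.
#' @return An `es_geom`.
#' @export
geom_rect <- function(xmin, ymin, xmax, ymax, crs = "local") {
  es_geom(cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin)), crs = crs)
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Planar area of a geometry (exterior minus holes)
#' @param geom an `es_geom`.
#' @return Area in squared CRS units.
#' @export
geom_area <- function(geom) {
  sum(vapply(geom$polys, function(p) {
    a <- ring_area(p[[1]])
    if (length(p) > 1)
      a <- a - sum(vapply(p[-1], ring_area, numeric(1)))
    a
  }, numeric(1)))
}

geom_bbox <- function(geom) {
  xs <- unlist(lapply(geom$polys, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geom$polys, function(p) lapply(p, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Even-odd containment of points in a multipolygon. Edge/vertex hits count as
# inside. Returns a logical vector.
points_in_geom <- function(x, y, geom) {
  inside <- rep(FALSE, length(x))
  for (p in geom$polys) {
    in_ext <- sp::point.in.polygon(x, y, p[[1]][, 1], p[[1]][, 2]) > 0
    if (length(p) > 1) {
      for (hole in p[-1]) {
        # strictly interior to a hole -> excluded; hole boundary still inside
        in_hole <- sp::point.in.polygon(x, y, hole[, 1], hole[, 2]) == 1
        in_ext <- in_ext & !in_hole
      }
    }
    inside <- inside | in_ext
  }
  inside
}

#' Administrative zone sets
#'
#' Nested zones at up to three levels (`national`, `regional`,
#' `sub_regional`). Every `sub_regional` zone must name an existing
#' `regional` parent. Geometries at one level are expected to be
#' non-overlapping; overlapping pixel assignments are detected (and warned
#' about) when zones are rasterized.
#'
#' @param zone_id,name,level,parent_id character vectors, one entry per zone;
#'   `level` entries must be in `c("national","regional","sub_regional")`.
#' @param geometry list of `es_geom`, one per zone.
#' @return An object of class `es_zoneset`: a data.frame with a `geometry`
#'   list column.
#' @export
es_zoneset <- function(zone_id, name, level, parent_id, geometry) {
  zone_id <- as.character(zone_id)
  if (anyDuplicated(zone_id)) abort("zone_ids must be unique", "validation")
  lv <- c("national", "regional", "sub_regional")
  if (!all(level %in% lv))
    abort("zone level must be national, regional or sub_regional",
          "validation")
  sub <- level == "sub_regional"
  if (any(sub & !(parent_id %in% zone_id[level == "regional"])))
    abort("every sub_regional zone needs an existing regional parent_id",
          "validation")
  df <- data.frame(zone_id = zone_id, name = as.character(name),
                   level = as.character(level),
                   parent_id = as.character(parent_id),
                   stringsAsFactors = FALSE)
  df$geometry <- geometry
  structure(df, class = c("es_zoneset", "data.frame"))
}

#' @export
print.es_zoneset <- function(x, ...) {
  cat(sprintf("<es_zoneset> %d zones (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$level)), table(x$level)),
                    collapse = ", ")))
  invisible(x)
}

zones_at_level <- function(zones, level) zones[zones$level == level, ]

# Rasterize a zone level: integer matrix of row indices into `zones`
# (NA = outside all zones at that level), by pixel-center point-in-polygon.
zone_index <- function(zones, grid, level) {
  zs <- zones_at_level(zones, level)
  idx <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  if (!nrow(zs)) return(idx)
  xs <- col_centers_x(grid); ys <- row_centers_y(grid)
  overlap <- 0L
  for (k in seq_len(nrow(zs))) {
    g <- zs$geometry[[k]]
    if (g$crs != grid$crs)
      abort(sprintf("zone '%s' CRS (%s) differs from raster CRS (%s)",
                    zs$zone_id[k], g$crs, grid$crs), "contract")
    bb <- geom_bbox(g)
    ci <- which(xs >= bb["xmin"] & xs <= bb["xmax"])
    ri <- which(ys >= bb["ymin"] & ys <= bb["ymax"])
    if (!length(ci) || !length(ri)) next
    pts <- expand.grid(r = ri, c = ci)
    hit <- points_in_geom(xs[pts$c], ys[pts$r], g)
    cells <- cbind(pts$r[hit], pts$c[hit])
    overlap <- overlap + sum(!is.na(idx[cells]))
    idx[cells] <- k
  }
  if (overlap > 0)
    warning(sprintf("%d pixels fall in more than one '%s' zone; last assignment wins",
                    overlap, level), call. = FALSE)
  idx
}

# ---- GeoJSON IO --------------------------------------------------------

ring_to_coords <- function(ring) {
  # close the ring for GeoJSON
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Read / write zone sets as GeoJSON
#'
#' Features carry properties `zone_id`, `name`, `level`, `parent_id` and a
#' `Polygon` or `MultiPolygon` geometry. The CRS id is stored in the
#' (legacy-style) top-level `crs` member and defaults to `"local"`.
#'
#' @param path file path.
#' @return `read_zones` returns an `es_zoneset`.
#' @export
read_zones <- function(path) {
  if (!file.exists(path)) abort(paste("zones file not found:", path), "io")
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  crs <- tryCatch(j$crs$properties$name %||% "local", error = function(e) "local")
  feats <- j$features
  if (is.null(feats)) abort("not a GeoJSON FeatureCollection", "io")
  as_ring <- function(coords)
    do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    polys <- switch(g$type,
      Polygon = list(lapply(g$coordinates, as_ring)),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, as_ring)),
      abort(paste("unsupported geometry type:", g$type), "io"))
    es_geom(polys, crs = crs)
  })
  prop <- function(field, default = "")
    vapply(feats, function(f) as.character(f$properties[[field]] %||% default),
           character(1))
  es_zoneset(prop("zone_id"), prop("name"), prop("level"), prop("parent_id"),
             geoms)
}

#' @rdname read_zones
#' @param zones an `es_zoneset`.
#' @export
write_zones <- function(zones, path) {
  crs <- zones$geometry[[1]]$crs
  feats <- lapply(seq_len(nrow(zones)), function(k) {
    g <- zones$geometry[[k]]
    coords <- lapply(g$polys, function(p) lapply(p, ring_to_coords))
    geometry <- if (length(g$polys) == 1)
      list(type = "Polygon", coordinates = coords[[1]])
    else
      list(type = "MultiPolygon", coordinates = coords)
    list(type = "Feature",
         properties = list(zone_id = zones$zone_id[k], name = zones$name[k],
                           level = zones$level[k],
                           parent_id = zones$parent_id[k]),
         geometry = geometry)
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs)),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
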