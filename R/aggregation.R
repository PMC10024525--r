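#' Equal-weight overall ES supply aggregate
#'
#' Sums the per-service score rasters of one (variant, year) combination with
#' equal weights, then standardizes the sum. A pixel is valid only if it is
#' valid in every service (classes with missing scores propagate nodata), so
#' the sum is never taken over unequal service sets.
#'
#' Standardization: `"minmax"` (default) rescales the raw sum over valid
#' pixels to [0,1]; an all-constant raw map standardizes to all zeros.
#' `"theoretical"` divides by `5 * n_services`, the maximum attainable sum.
#'
#' @param stack list of `es_score_raster`, one per service, sharing grid,
#'   variant and year.
#' @param standardize `"minmax"` or `"theoretical"`.
#' @return An object of class `es_aggregate` with fields `raw` and `std`
#'   (matrices), `grid`, `variant`, `year`, `n_services`.
#' @export
aggregate_overall <- function(stack, standardize = c("minmax", "theoretical")) {
  standardize <- match.arg(standardize)
  if (!length(stack)) abort("empty raster stack", "contract")
  svc <- vapply(stack, function(r) r$service, character(1))
  if (anyDuplicated(svc))
    abort(sprintf("duplicate service(s) in stack: %s",
                  paste(unique(svc[duplicated(svc)]), collapse = ", ")),
          "contract")
  ref <- stack[[1]]
  for (r in stack[-1]) {
    if (!grid_equal(r$grid, ref$grid))
      abort("stack rasters are on different grids", "alignment")
    if (r$variant != ref$variant || r$year != ref$year)
      abort("stack mixes variants or years", "contract")
  }
  raw <- Reduce(`+`, lapply(stack, `[[`, "values"))  # NA propagates
  valid <- !is.na(raw)
  std <- raw
  if (any(valid)) {
    if (standardize == "minmax") {
      lo <- min(raw[valid]); hi <- max(raw[valid])
      std[valid] <- if (hi > lo) (raw[valid] - lo) / (hi - lo) else 0
    } else {
      std[valid] <- raw[valid] / (5 * length(stack))
    }
  }
  structure(list(raw = raw, std = std, grid = ref$grid,
                 variant = ref$variant, year = ref$year,
                 n_services = length(stack)),
            class = "es_aggregate")
}

# Accept either an es_score_raster or an es_aggregate (standardized surface
# summarized on the raw scale would mix units; zonal stats on aggregates use
# the raw sum, matching "total potential" in score.km2).
zonal_input <- function(r) {
  if (inherits(r, "es_aggregate"))
    list(values = r$raw, grid = r$grid, service = "OVERALL",
         variant = r$variant, year = r$year)
  else
    list(values = r$values, grid = r$grid, service = r$service,
         variant = r$variant, year = r$year)
}

#' Area-weighted zonal statistics of a score surface
#'
#' Per zone (at every level of the zone set):
#' `mean_per_unit_area = sum(score * pixel_area) / sum(pixel_area)` and
#' `total_potential = sum(score * pixel_area)` (score.km2), over valid pixels
#' whose centers fall in the zone. A zone with no valid pixel yields an `NA`
#' mean and zero total.
#'
#' @param r an `es_score_raster` or `es_aggregate`.
#' @param zones an `es_zoneset`.
#' @param areas an `es_pixel_areas`.
#' @return A data.frame with columns `zone_id`, `level`, `service_code`,
#'   `variant`, `year`, `mean_per_unit_area`, `total_potential`,
#'   `valid_area_km2`.
#' @export
zonal_mean <- function(r, zones, areas) {
  ri <- zonal_input(r)
  w <- area_weights(areas, ri$grid)
  vals <- ri$values
  rows <- list()
  for (lv in intersect(c("national", "regional", "sub_regional"),
                       unique(zones$level))) {
    zidx <- zone_index(zones, ri$grid, lv)
    zs <- zones_at_level(zones, lv)
    for (k in seq_len(nrow(zs))) {
      inz <- !is.na(zidx) & zidx == k
      ok <- inz & !is.na(vals)
      tot <- sum(vals[ok] * w[ok])
      va <- sum(w[ok])
      rows[[paste(lv, k)]] <- data.frame(
        zone_id = zs$zone_id[k], level = lv, service_code = ri$service,
        variant = ri$variant, year = ri$year,
        mean_per_unit_area = if (va > 0) tot / va else NA_real_,
        total_potential = tot, valid_area_km2 = va,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Zonal summary of a whole score stack
#'
#' Runs [zonal_mean()] for every raster of a stack plus the equal-weight
#' aggregate of each (variant, year) and binds the rows.
#'
#' @param stack list of `es_score_raster` (as from [score_stack()]).
#' @param zones an `es_zoneset`.
#' @param areas an `es_pixel_areas`.
#' @param standardize passed to [aggregate_overall()].
#' @return A `SummaryTable` data.frame (see [zonal_mean()]).
#' @export
summarize_stack <- function(stack, zones, areas,
                            standardize = "minmax") {
  keys <- vapply(stack, function(r) paste(r$variant, r$year), character(1))
  parts <- lapply(stack, zonal_mean, zones = zones, areas = areas)
  for (k in unique(keys)) {
    agg <- aggregate_overall(stack[keys == k], standardize = standardize)
    parts[[paste0("agg_", k)]] <- zonal_mean(agg, zones, areas)
  }
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Change in zonal means relative to a baseline year
#'
#' Joins a summary table with itself on (zone, service, variant):
#' `change_vs_baseline = mean(year) - mean(baseline)`. The `OVERALL` row per
#' zone/variant/year is recomputed as the unweighted mean of the per-service
#' means ("equal weights to each ES"), with its own change. Keys present in
#' one year only get an `NA` change and a warning.
#'
#' @param table a summary table covering the baseline and target year(s).
#' @param baseline_year the reference year.
#' @param overall one of `"service_means"` (default: OVERALL = unweighted
#'   mean of the per-service means) or `"aggregate_raster"` (keep the zonal
#'   mean of the raw aggregate surface as the OVERALL row).
#' @return The table with an added `change_vs_baseline` column (full
#'   precision; round at report time).
#' @export
summarize_changes <- function(table, baseline_year,
                              overall = c("service_means",
                                          "aggregate_raster")) {
  overall <- match.arg(overall)
  dt <- data.table::as.data.table(table)
  if (overall == "service_means") {
    per_svc <- dt[service_code != "OVERALL"]
    ov <- per_svc[, .(mean_per_unit_area = mean(mean_per_unit_area),
                      total_potential = sum(total_potential),
                      valid_area_km2 = valid_area_km2[1],
                      service_code = "OVERALL"),
                  by = .(zone_id, level, variant, year)]
    dt <- rbind(per_svc, ov, use.names = TRUE, fill = TRUE)
  }
  if (!baseline_year %in% dt$year)
    abort(sprintf("baseline year %d not present in the table", baseline_year),
          "contract")
  base <- dt[year == baseline_year,
             .(zone_id, service_code, variant, base_mean = mean_per_unit_area)]
  out <- merge(dt, base, by = c("zone_id", "service_code", "variant"),
               all.x = TRUE)
  orphan <- is.na(out$base_mean) & !is.na(out$mean_per_unit_area)
  if (any(orphan))
    warning(sprintf("%d summary keys have no baseline-year counterpart; change set to NA",
                    sum(orphan)), call. = FALSE)
  out[, change_vs_baseline := mean_per_unit_area - base_mean]
  out[, base_mean := NULL]
  data.table::setorder(out, level, zone_id, variant, service_code, year)
  as.data.frame(out)
}

#' Rank services by mean potential supply in a zone
#'
#' Descending by `mean_per_unit_area`; ties broken by service code ascending.
#'
#' @param table a summary table.
#' @param zone_id,year,variant the key to rank within.
#' @return Character vector of the 10 service codes, best first.
#' @export
rank_services <- function(table, zone_id, year, variant) {
  sel <- table$zone_id == zone_id & table$year == year &
    table$variant == variant & table$service_code %in% es_services()$code
  sub <- table[sel, ]
  missing <- setdiff(es_services()$code, sub$service_code)
  if (length(missing))
    abort(sprintf("summary lacks service(s) %s for zone %s",
                  paste(missing, collapse = ", "), zone_id), "contract")
  sub$service_code[order(-sub$mean_per_unit_area, sub$service_code)]
}

# Report-time rounding: means/changes to 2 decimals, totals and areas to
# whole units; computation upstream stays full precision.
round_summary <- function(table) {
  for (col in c("mean_per_unit_area", "change_vs_baseline"))
    if (col %in% names(table)) table[[col]] <- round(table[[col]], 2)
  for (col in c("total_potential", "valid_area_km2", "area_km2",
                "net_change_km2"))
    if (col %in% names(table)) table[[col]] <- round(table[[col]])
  if ("percent_change" %in% names(table))
    table$percent_change <- round(table$percent_change, 1)
  table
}
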