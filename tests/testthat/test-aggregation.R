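mk_score <- function(vals, service, variant = "max", year = 2019,
                     cell = 100) {
  vals <- as.matrix(vals)
  es_score_raster(vals, toy_grid(nrow(vals), ncol(vals), cell),
                  service, variant, year)
}

test_that("aggregate_overall sums with equal weights and standardizes", {
  # constant raw map -> all-zero standardized (degenerate min-max rule)
  a <- mk_score(rbind(c(1, 3)), "a")
  b <- mk_score(rbind(c(2, 0)), "b")
  agg <- aggregate_overall(list(a, b))
  expect_equal(agg$raw, rbind(c(3, 3)))
  expect_equal(agg$std, rbind(c(0, 0)))

  # min-max endpoints
  agg2 <- aggregate_overall(list(mk_score(rbind(c(2, 7)), "a")))
  expect_equal(agg2$std, rbind(c(0, 1)))

  # single all-zero service
  agg3 <- aggregate_overall(list(mk_score(matrix(0, 2, 2), "a")))
  expect_true(all(agg3$raw == 0) && all(agg3$std == 0))

  # nodata in any service propagates; theoretical scaling divides by 5K
  a2 <- mk_score(rbind(c(1, NA)), "a")
  agg4 <- aggregate_overall(list(a2, b), standardize = "theoretical")
  expect_true(is.na(agg4$raw[1, 2]))
  expect_equal(agg4$std[1, 1], 3 / 10)

  expect_error(aggregate_overall(list(a, mk_score(rbind(c(1, 1)), "a"))),
               class = "esmapr_contract_error")
  expect_error(
    aggregate_overall(list(a, mk_score(rbind(c(1, 1)), "b", year = 2015))),
    class = "esmapr_contract_error")
})

test_that("zonal_mean is the area-weighted mean over valid zone pixels", {
  zones <- es_zoneset("Z", "zone", "regional", "",
                      list(geom_rect(0, 0, 100, 200)))
  # 2x1 raster, one zone covering it; pixel areas differ by row
  g <- toy_grid(2, 1)
  r <- es_score_raster(matrix(c(4, 1), 2, 1), g, "a", "max", 2019)
  ar <- structure(list(mode = "nominal", nominal_area_km2 = NA,
                       per_row_area_km2 = c(1, 3), n_rows = 2),
                  class = "es_pixel_areas")
  zm <- zonal_mean(r, zones, ar)
  expect_equal(zm$mean_per_unit_area, (4 * 1 + 1 * 3) / 4)
  expect_equal(zm$total_potential, 7)

  # equal areas: mean 2.5, total 5 * unit area
  r2 <- mk_score(rbind(c(4, 1)), "a")
  z2 <- es_zoneset("Z", "zone", "regional", "",
                   list(geom_rect(0, 0, 200, 100)))
  zm2 <- zonal_mean(r2, z2, unit_areas(r2$grid))
  expect_equal(zm2$mean_per_unit_area, 2.5)
  expect_equal(zm2$total_potential, 5)

  # all-nodata zone: NA mean, zero total
  r3 <- mk_score(rbind(c(NA, NA)), "a")
  zm3 <- zonal_mean(r3, z2, unit_areas(r3$grid))
  expect_true(is.na(zm3$mean_per_unit_area))
  expect_equal(zm3$total_potential, 0)
})

test_that("zonal_mean matches the per-pixel oracle on random rasters", {
  set.seed(31)
  for (k in 1:5) {
    nr <- sample(10:50, 1); nc <- sample(10:50, 1)
    g <- toy_grid(nr, nc)
    vals <- matrix(runif(nr * nc, 0, 5), nr, nc)
    vals[sample(nr * nc, round(0.1 * nr * nc))] <- NA
    r <- es_score_raster(vals, g, "a", "max", 2019)
    zones <- generate_zones(g, n_regions = 3, subs_per_region = 2)
    ar <- unit_areas(g)
    zm <- zonal_mean(r, zones, ar)
    oracle <- bf_zonal(vals, g, ar, zone_rects(zones, "sub_regional"))
    for (z in names(oracle)) {
      row <- zm[zm$zone_id == z, ]
      expect_equal(row$mean_per_unit_area, oracle[[z]][["mean"]])
      expect_equal(row$total_potential, oracle[[z]][["total"]])
    }
  }
})

test_that("summarize_changes differences means against the baseline", {
  base <- data.frame(zone_id = "Z", level = "national",
                     service_code = c("a", "b"), variant = "max",
                     year = 2015, mean_per_unit_area = c(2.00, 1.50),
                     total_potential = c(20, 15), valid_area_km2 = 10)
  tgt <- base
  tgt$year <- 2019
  tgt$mean_per_unit_area <- c(2.19, 1.50)
  ch <- summarize_changes(rbind(base, tgt), 2015)
  get <- function(s, y) ch$change_vs_baseline[ch$service_code == s &
                                                ch$year == y]
  expect_equal(get("a", 2019), 0.19)
  expect_equal(get("b", 2019), 0)
  expect_equal(get("a", 2015), 0)

  # OVERALL = unweighted mean of service means, with its own change
  ov19 <- ch[ch$service_code == "OVERALL" & ch$year == 2019, ]
  expect_equal(ov19$mean_per_unit_area, mean(c(2.19, 1.50)))
  expect_equal(ov19$change_vs_baseline,
               mean(c(2.19, 1.50)) - mean(c(2.00, 1.50)))

  # identical years -> all changes 0
  same <- tgt; same$mean_per_unit_area <- base$mean_per_unit_area
  ch0 <- summarize_changes(rbind(base, same), 2015)
  expect_true(all(ch0$change_vs_baseline == 0))

  # key missing in the baseline year -> NA change + warning
  extra <- tgt[1, ]; extra$service_code <- "c"
  expect_warning(chna <- summarize_changes(rbind(base, tgt, extra), 2015),
                 "no baseline")
  expect_true(is.na(chna$change_vs_baseline[chna$service_code == "c"]))
})

test_that("rank_services sorts by mean, ties by code", {
  tb <- data.frame(zone_id = "Z", level = "national",
                   service_code = letters[1:10], variant = "max",
                   year = 2019,
                   mean_per_unit_area = c(1, 3, 2, rep(0.5, 7)),
                   total_potential = 0, valid_area_km2 = 1)
  expect_equal(rank_services(tb, "Z", 2019, "max")[1:3], c("b", "c", "a"))

  tb$mean_per_unit_area <- 1
  expect_equal(rank_services(tb, "Z", 2019, "max"), letters[1:10])

  set.seed(8)
  tb$mean_per_unit_area <- runif(10)
  naive <- tb$service_code[order(tb$mean_per_unit_area,
                                 decreasing = TRUE)]
  expect_equal(rank_services(tb, "Z", 2019, "max"), naive)

  expect_error(rank_services(tb[-1, ], "Z", 2019, "max"),
               class = "esmapr_contract_error")
})

test_that("greening monotonicity: services gain iff score(30) > score(60)", {
  leg <- cglc_legend()
  mat <- synthetic_es_matrix(legend = leg)
  cfg <- landscape_config(es_grid(60, 60, 100, -100, 0, 6000), seed = 17,
                          n_patches = 120)
  lc1 <- generate_landscape(cfg, year = 2015)
  # convert a batch of bare pixels to herbaceous, nothing else
  vals2 <- lc1$values
  bare <- which(vals2 == 60L)
  vals2[bare[seq_len(min(300, length(bare)))]] <- 30L
  lc2 <- es_landcover(vals2, lc1$grid, 2019, leg)
  zones <- es_zoneset("NAT", "n", "national", "",
                      list(geom_rect(0, 0, 6000, 6000)))
  ar <- pixel_areas(lc1$grid, "nominal", nominal_area_km2 = 0.01)
  stack <- score_stack(list(lc1, lc2), mat, variants = "max",
                       years = c(2015, 2019))
  summary <- summarize_stack(stack, zones, ar)
  ch <- summarize_changes(summary, 2015)
  sc <- function(code, svc)
    mat$max_score[mat$class_code == code & mat$service_code == svc]
  for (s in es_services()$code) {
    d <- ch$change_vs_baseline[ch$service_code == s & ch$year == 2019]
    if (sc(30, s) > sc(60, s)) expect_gt(d, 0)
    if (sc(30, s) == sc(60, s)) expect_equal(d, 0)
    if (sc(30, s) < sc(60, s)) expect_lt(d, 0)
  }
})

test_that("hierarchical consistency of zonal totals and means", {
  set.seed(23)
  g <- toy_grid(40, 40)
  vals <- matrix(runif(1600, 0, 5), 40, 40)
  r <- es_score_raster(vals, g, "a", "max", 2019)
  zones <- generate_zones(g, n_regions = 4, subs_per_region = 5)
  ar <- unit_areas(g)
  zm <- zonal_mean(r, zones, ar)
  nat <- zm[zm$level == "national", ]
  reg <- zm[zm$level == "regional", ]
  sub <- zm[zm$level == "sub_regional", ]
  expect_equal(sum(reg$total_potential), nat$total_potential,
               tolerance = 1e-9)
  expect_equal(sum(reg$mean_per_unit_area * reg$valid_area_km2) /
                 sum(reg$valid_area_km2),
               nat$mean_per_unit_area, tolerance = 1e-9)
  for (rid in zones$zone_id[zones$level == "regional"]) {
    kids <- zones$zone_id[zones$parent_id == rid]
    expect_equal(sum(sub$total_potential[sub$zone_id %in% kids]),
                 reg$total_potential[reg$zone_id == rid], tolerance = 1e-9)
  }
})
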