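test_that("class_areas sums pixel areas per class, nationally and per zone", {
  lc <- toy_lc(rbind(c(60L, 60L), c(30L, 40L)))
  ar <- unit_areas(lc$grid)
  at <- class_areas(lc, ar)
  get <- function(code) at$area_km2[at$class_code == code]
  expect_equal(get(60), 2)
  expect_equal(get(30), 1)
  expect_equal(get(40), 1)
  expect_equal(get(20), 0)
  expect_equal(sum(at$area_km2), 4)  # = valid area

  # two one-column zones: west gets column 1, east column 2
  zones <- es_zoneset(c("W", "E"), c("west", "east"),
                      c("regional", "regional"), c("", ""),
                      list(geom_rect(0, 0, 100, 200),
                           geom_rect(100, 0, 200, 200)))
  atz <- class_areas(lc, ar, zones)
  w <- atz[atz$zone_id == "W", ]
  e <- atz[atz$zone_id == "E", ]
  expect_equal(w$area_km2[w$class_code == 60], 1)
  expect_equal(w$area_km2[w$class_code == 30], 1)
  expect_equal(e$area_km2[e$class_code == 60], 1)
  expect_equal(e$area_km2[e$class_code == 40], 1)
})

test_that("transition_matrix enumerates pixel transitions", {
  ar <- unit_areas(toy_grid())
  lc_a <- toy_lc(rbind(c(60L, 60L), c(30L, 40L)), year = 2015)

  # identity: purely diagonal, diagonal = class areas
  lc_same <- toy_lc(lc_a$values, year = 2016)
  tm0 <- transition_matrix(lc_a, lc_same, ar)
  expect_equal(tm0$cells["60", "60"], 2)
  expect_equal(sum(tm0$cells) , sum(diag(tm0$cells)))

  # hand-enumerated 4-pixel case
  lc_b <- toy_lc(rbind(c(30L, 60L), c(30L, 40L)), year = 2019)
  tm <- transition_matrix(lc_a, lc_b, ar)
  expect_equal(tm$cells["60", "30"], 1)
  expect_equal(tm$cells["60", "60"], 1)
  expect_equal(tm$cells["30", "30"], 1)
  expect_equal(tm$cells["40", "40"], 1)
  expect_equal(sum(tm$cells), 4)

  # nodata in either year is excluded and reported
  lc_c <- toy_lc(rbind(c(0L, 60L), c(30L, 40L)), year = 2020)
  tm2 <- transition_matrix(lc_a, lc_c, ar)
  expect_equal(sum(tm2$cells), 3)
  expect_equal(tm2$excluded_km2, 1)

  expect_error(transition_matrix(lc_b, lc_a, ar),
               class = "esmapr_contract_error")
  wide <- es_landcover(matrix(60L, 2, 3), toy_grid(2, 3), 2019, toy_legend())
  expect_error(transition_matrix(lc_a, wide, ar),
               class = "esmapr_alignment_error")
})

test_that("net_change is column minus row sums and conserves area", {
  ar <- unit_areas(toy_grid())
  lc_a <- toy_lc(rbind(c(60L, 60L), c(30L, 40L)), year = 2015)
  lc_b <- toy_lc(rbind(c(30L, 60L), c(30L, 40L)), year = 2019)
  nc <- net_change(transition_matrix(lc_a, lc_b, ar))
  expect_equal(nc[["60"]], -1)
  expect_equal(nc[["30"]], 1)
  expect_equal(nc[["40"]], 0)

  set.seed(42)
  for (k in 1:20) {
    a <- rand_lc(8, 8, 2015)
    b <- rand_lc(8, 8, 2016)
    b$values <- matrix(sample(c(toy_legend()$class_code, 0L), 64,
                              replace = TRUE), 8, 8)
    tm <- transition_matrix(a, b, unit_areas(a$grid))
    expect_lt(abs(sum(net_change(tm))), 1e-9)
  }
})

test_that("change_table computes net and percent change vs baseline", {
  leg <- toy_legend()
  # baseline: 100 px of 30; later: 188 px of 30 -> +88%
  g <- toy_grid(20, 20)
  v1 <- matrix(60L, 20, 20); v1[1:100] <- 30L
  v2 <- matrix(60L, 20, 20); v2[1:188] <- 30L
  s <- list(es_landcover(v1, g, 2015, leg), es_landcover(v2, g, 2019, leg))
  ct <- change_table(s, 2015, unit_areas(g))
  r30 <- ct[ct$class_code == 30 & ct$year == 2019, ]
  expect_equal(r30$net_change_km2, 88)
  expect_equal(r30$percent_change, 88)

  # zero baseline -> net reported, percent NA
  r20 <- ct[ct$class_code == 20 & ct$year == 2019, ]
  expect_equal(r20$net_change_km2, 0)
  v2b <- v2; v2b[400] <- 20L
  ct2 <- change_table(list(s[[1]], es_landcover(v2b, g, 2019, leg)),
                      2015, unit_areas(g))
  r20b <- ct2[ct2$class_code == 20 & ct2$year == 2019, ]
  expect_equal(r20b$net_change_km2, 1)
  expect_true(is.na(r20b$percent_change))

  # constant series -> all zeros
  s3 <- list(es_landcover(v1, g, 2015, leg), es_landcover(v1, g, 2017, leg))
  ct3 <- change_table(s3, 2015, unit_areas(g))
  expect_true(all(ct3$net_change_km2 == 0))
  expect_true(all(ct3$percent_change[!is.na(ct3$percent_change)] == 0))

  expect_error(change_table(s, 2014, unit_areas(g)),
               class = "esmapr_contract_error")
})

test_that("chained transitions are consistent on a fixed valid mask", {
  # for years a < b < c with no nodata: colSums T(a->b) = rowSums T(b->c)
  set.seed(7)
  for (k in 1:10) {
    a <- rand_lc(12, 9, 2015, p_nodata = 0)
    b <- rand_lc(12, 9, 2016, p_nodata = 0)
    cc <- rand_lc(12, 9, 2017, p_nodata = 0)
    ar <- unit_areas(a$grid)
    t_ab <- transition_matrix(a, b, ar)
    t_bc <- transition_matrix(b, cc, ar)
    expect_equal(colSums(t_ab$cells), rowSums(t_bc$cells))
    # and row/col sums tie out to the per-year class areas
    ca <- class_areas(a, ar)
    expect_equal(unname(rowSums(t_ab$cells)),
                 ca$area_km2[match(rownames(t_ab$cells), ca$class_code)])
  }
})

test_that("national transition equals the sum over tiling zones", {
  set.seed(11)
  a <- rand_lc(30, 30, 2015)
  b <- rand_lc(30, 30, 2019)
  ar <- unit_areas(a$grid)
  zones <- generate_zones(a$grid, n_regions = 4, subs_per_region = 3)
  national <- transition_matrix(a, b, ar)$cells
  reg <- zones[zones$level == "regional", ]
  reg_sum <- Reduce(`+`, lapply(reg$geometry, function(g)
    transition_matrix(a, b, ar, zone = g)$cells))
  expect_equal(reg_sum, national, tolerance = 1e-9)
  # each region = sum of its sub-regions
  for (rid in reg$zone_id) {
    subs <- zones[zones$parent_id == rid & zones$level == "sub_regional", ]
    sub_sum <- Reduce(`+`, lapply(subs$geometry, function(g)
      transition_matrix(a, b, ar, zone = g)$cells))
    reg_m <- transition_matrix(a, b, ar,
                               zone = reg$geometry[[match(rid, reg$zone_id)]])
    expect_equal(sub_sum, reg_m$cells, tolerance = 1e-9)
  }
})

test_that("class_areas and transition_matrix match the per-pixel oracle", {
  set.seed(99)
  for (k in 1:10) {
    nr <- sample(5:40, 1); nc <- sample(5:40, 1)
    a <- rand_lc(nr, nc, 2015)
    b <- rand_lc(nr, nc, 2016)
    ar <- unit_areas(a$grid)
    ca <- class_areas(a, ar)
    expect_equal(setNames(ca$area_km2, ca$class_code), bf_class_areas(a, ar))
    tm <- transition_matrix(a, b, ar)
    expect_equal(unname(tm$cells), unname(bf_transition(a, b, ar)))
  }
})
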