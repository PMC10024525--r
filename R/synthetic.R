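#' Synthetic landscape configuration
#'
#' The generator emulates a CGLC-style arid landscape: 11 integer classes
#' whose default shares mirror the study region (about 50% bare/sparse,
#' 26.5% shrubs, 17.2% herbaceous, 5.6% cropland, the rest split among minor
#' classes), on a projected 100 m grid, as a Voronoi patch mosaic so land
#' cover is spatially autocorrelated rather than salt-and-pepper.
#'
#' @param grid an `es_grid` (projected; nominal pixel areas apply).
#' @param class_proportions named numeric vector (names = class codes),
#'   non-negative, summing to 1 within 1e-9.
#' @param n_patches number of Voronoi seed patches (granularity control);
#'   at most `n_rows * n_cols`.
#' @param seed integer RNG seed.
#' @param legend an `es_legend` covering the proportion codes.
#' @return An object of class `es_landscape_config`.
#' @export
landscape_config <- function(grid = default_grid(),
                             class_proportions = default_proportions(),
                             n_patches = 2000, seed = 1,
                             legend = cglc_legend()) {
  p <- class_proportions
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    abort("class proportions must be non-negative and sum to 1", "validation")
  if (!all(as.integer(names(p)) %in% legend_codes(legend)))
    abort("proportion codes must be legend class codes", "validation")
  if (n_patches > grid$n_rows * grid$n_cols)
    abort("more patches than pixels", "contract")
  structure(list(grid = grid, class_proportions = p,
                 n_patches = as.integer(n_patches), seed = as.integer(seed),
                 legend = legend),
            class = "es_landscape_config")
}

#' @rdname landscape_config
#' @export
default_grid <- function() {
  # 500 x 500 pixels at 100 m on a local projected CRS: 2500 km2, the scale
  # at which patch statistics are well resolved but everything runs in seconds
  es_grid(500, 500, pixel_width = 100, pixel_height = -100,
          origin_x = 0, origin_y = 50000, crs = "local")
}

#' @rdname landscape_config
#' @export
default_proportions <- function() {
  c(`60` = 0.500, `20` = 0.265, `30` = 0.172, `40` = 0.056,
    `126` = 0.004, `50` = 0.001,
    `80` = 0.0006, `90` = 0.0004, `114` = 0.0004, `116` = 0.0003,
    `124` = 0.0003)
}

#' Default "greening" Markov transitions
#'
#' One-step yearly transition probabilities dominated by bare/sparse (60) to
#' herbaceous (30) conversion at 1.9% per year -- about 7.5% of the bare
#' class over four steps, the magnitude of the documented national greening
#' signal -- with small secondary flows into wetland (90) and water (80).
#' All other classes persist.
#'
#' @param legend an `es_legend`.
#' @return Row-stochastic K x K matrix, dimnames = class codes.
#' @export
default_transitions <- function(legend = cglc_legend()) {
  codes <- legend_codes(legend)
  P <- diag(length(codes))
  dimnames(P) <- list(from = codes, to = codes)
  P["60", "30"] <- 0.019
  P["60", "90"] <- 0.0004
  P["60", "80"] <- 0.0006
  P["60", "60"] <- 1 - 0.019 - 0.0004 - 0.0006
  P["20", "30"] <- 0.002
  P["20", "20"] <- 1 - 0.002
  P
}

check_stochastic <- function(P) {
  if (any(P < 0) || any(P > 1))
    abort("transition probabilities must be in [0,1]", "validation")
  bad <- which(abs(rowSums(P) - 1) > 1e-9)
  if (length(bad))
    abort(sprintf("transition row(s) not stochastic: %s",
                  paste(rownames(P)[bad], collapse = ", ")), "validation")
  invisible(P)
}

# Nearest-seed (Voronoi) labelling. Exact brute force, but phrased as
# argmin(|s|^2 - 2 p.s) so the heavy part is one BLAS matrix product per
# chunk (|p|^2 is constant per pixel and drops out of the argmin); chunking
# keeps the pixel x seed score matrix small.
nearest_seed <- function(px, py, sx, sy, chunk = 5000L) {
  S <- rbind(sx, sy)
  s2 <- sx^2 + sy^2
  n <- length(px)
  out <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    score <- cbind(px[lo:hi], py[lo:hi]) %*% S          # k x m dot products
    score <- score - rep(s2 / 2, each = hi - lo + 1L)
    out[lo:hi] <- max.col(score, ties.method = "first")
  }
  out
}

#' Generate a patchy synthetic land-cover raster
#'
#' Draws `n_patches` seed points uniformly over the extent, assigns each
#' patch a class sampled from the configured proportions, and labels every
#' pixel with the class of its nearest seed (a Voronoi mosaic). Deterministic
#' for a given seed; realized class shares converge on the configured
#' proportions as the patch count grows.
#'
#' @param cfg an `es_landscape_config`.
#' @param year year stamped on the raster.
#' @return An `es_landcover`.
#' @export
generate_landscape <- function(cfg, year = 2015) {
  grid <- cfg$grid
  with_seed(cfg$seed, {
    xmin <- grid$origin_x
    xmax <- grid$origin_x + grid$n_cols * grid$pixel_width
    ytop <- grid$origin_y
    ybot <- grid$origin_y + grid$n_rows * grid$pixel_height
    sx <- stats::runif(cfg$n_patches, min(xmin, xmax), max(xmin, xmax))
    sy <- stats::runif(cfg$n_patches, min(ytop, ybot), max(ytop, ybot))
    codes <- as.integer(names(cfg$class_proportions))
    # sample.int: immune to sample()'s scalar-x expansion when one class left
    patch_class <- codes[sample.int(length(codes), cfg$n_patches,
                                    replace = TRUE,
                                    prob = cfg$class_proportions)]
    pts <- expand.grid(y = row_centers_y(grid), x = col_centers_x(grid))
    lab <- nearest_seed(pts$x, pts$y, sx, sy)
    vals <- matrix(patch_class[lab], grid$n_rows, grid$n_cols)
    es_landcover(vals, grid, year, cfg$legend)
  })
}

#' Evolve a landscape one step under Markov class transitions
#'
#' Every pixel's next class is drawn independently from the row of `P` for
#' its current class (no spatial coherence in change -- the simplest model
#' with an analytically known ground truth). Nodata pixels are unchanged.
#' Deterministic given the seed.
#'
#' @param lc an `es_landcover`.
#' @param P row-stochastic matrix indexed by the raster's legend codes.
#' @param seed integer RNG seed.
#' @param year year stamped on the result (default `lc$year + 1`).
#' @return An `es_landcover`.
#' @export
apply_transitions <- function(lc, P, seed, year = lc$year + 1) {
  codes <- legend_codes(lc$legend)
  if (is.null(rownames(P)) ||
      !setequal(rownames(P), as.character(codes)) ||
      !setequal(colnames(P), as.character(codes)))
    abort("P must be indexed by the raster's legend codes", "contract")
  P <- P[as.character(codes), as.character(codes)]
  check_stochastic(P)
  vals <- lc$values
  with_seed(seed, {
    for (r in seq_along(codes)) {
      sel <- which(lc$values == codes[r])
      if (!length(sel)) next
      vals[sel] <- codes[sample.int(length(codes), length(sel),
                                    replace = TRUE, prob = P[r, ])]
    }
  })
  es_landcover(vals, lc$grid, year, lc$legend)
}

#' Generate a synthetic multi-year land-cover series
#'
#' Year 1 from [generate_landscape()], later years by repeatedly applying
#' `P`; per-year RNG sub-seeds derive from the config seed by fixed offsets.
#'
#' @param cfg an `es_landscape_config`.
#' @param years increasing integer years.
#' @param P transition matrix (default [default_transitions()]).
#' @return List of `es_landcover`, one per year.
#' @export
generate_series <- function(cfg, years = 2015:2019,
                            P = default_transitions(cfg$legend)) {
  out <- list(generate_landscape(cfg, year = years[1]))
  for (k in seq_along(years)[-1]) {
    out[[k]] <- apply_transitions(out[[k - 1]], P,
                                  seed = sub_seed(cfg$seed, "transitions") + k,
                                  year = years[k])
  }
  names(out) <- years
  out
}

#' Generate nested rectangular administrative zones
#'
#' Tiles the grid extent into `n_regions` rectangles (arranged on a
#' near-square region grid), subdivides each region into `subs_per_region`
#' sub-regions, and adds one national zone covering the whole extent. Zones
#' tile the extent exactly and parent links are set. The default 6 x 10
#' layout stands in for a six-region / 57-sub-region administrative
#' hierarchy.
#'
#' @param grid an `es_grid`.
#' @param n_regions number of regions.
#' @param subs_per_region sub-regions per region.
#' @param seed unused at present (tiling is deterministic); kept so zone
#'   generation has the same (config, seed) signature as the other
#'   generators.
#' @return An `es_zoneset`.
#' @export
generate_zones <- function(grid, n_regions = 6, subs_per_region = 10,
                           seed = 1) {
  if (n_regions * subs_per_region < 1)
    abort("need at least one zone", "contract")
  if (n_regions * subs_per_region > grid$n_rows * grid$n_cols)
    abort("more zones than pixels", "contract")
  xmin <- grid$origin_x
  xmax <- grid$origin_x + grid$n_cols * grid$pixel_width
  ytop <- grid$origin_y
  ybot <- grid$origin_y + grid$n_rows * grid$pixel_height
  x0 <- min(xmin, xmax); x1 <- max(xmin, xmax)
  y0 <- min(ytop, ybot); y1 <- max(ytop, ybot)

  # snap split lines to pixel edges so no zone boundary can pass through a
  # pixel center: zones then tile the pixels exactly and zonal accounts are
  # additive without edge ambiguity
  snap_x <- function(v) x0 + round((v - x0) / abs(grid$pixel_width)) *
    abs(grid$pixel_width)
  snap_y <- function(v) y0 + round((v - y0) / abs(grid$pixel_height)) *
    abs(grid$pixel_height)
  split_rect <- function(x0r, x1r, y0r, y1r, n) {
    ncx <- ceiling(sqrt(n))
    ncy <- ceiling(n / ncx)
    xs <- snap_x(seq(x0r, x1r, length.out = ncx + 1))
    ys <- snap_y(seq(y0r, y1r, length.out = ncy + 1))
    cells <- list()
    k <- 0
    for (iy in seq_len(ncy)) for (ix in seq_len(ncx)) {
      if (k >= n) break
      k <- k + 1
      cells[[k]] <- c(xs[ix], ys[iy], xs[ix + 1], ys[iy + 1])
    }
    # fold surplus grid cells of the last row into the final zone
    if (ncx * ncy > n) cells[[n]][3] <- x1r
    cells
  }

  ids <- "NAT"; nms <- "National"; lvs <- "national"; par <- ""
  geoms <- list(geom_rect(x0, y0, x1, y1, crs = grid$crs))
  regions <- split_rect(x0, x1, y0, y1, n_regions)
  for (i in seq_len(n_regions)) {
    rid <- sprintf("R%02d", i)
    rc <- regions[[i]]
    ids <- c(ids, rid); nms <- c(nms, paste("Region", i))
    lvs <- c(lvs, "regional"); par <- c(par, "NAT")
    geoms <- c(geoms, list(geom_rect(rc[1], rc[2], rc[3], rc[4],
                                     crs = grid$crs)))
    subs <- split_rect(rc[1], rc[3], rc[2], rc[4], subs_per_region)
    for (j in seq_len(subs_per_region)) {
      sc <- subs[[j]]
      ids <- c(ids, sprintf("%sS%02d", rid, j))
      nms <- c(nms, sprintf("Region %d / Sub %d", i, j))
      lvs <- c(lvs, "sub_regional"); par <- c(par, rid)
      geoms <- c(geoms, list(geom_rect(sc[1], sc[2], sc[3], sc[4],
                                       crs = grid$crs)))
    }
  }
  es_zoneset(ids, nms, lvs, par, geoms)
}

#' Generate literature-style study matrices with known consensus
#'
#' Emulates a set of reviewed matrix-approach studies: a latent integer score
#' in 0-5 is drawn per (service, class); each study reports that score
#' perturbed by Gaussian noise, rounded, and clipped back into [0,5]. The
#' exact min/avg/max consensus of the realized studies is computed directly
#' from the score array (independently of [build_consensus_matrix()]) and
#' returned as ground truth.
#'
#' @param n_studies number of studies (the default 8 mirrors a typical
#'   reviewed-study count).
#' @param services service registry.
#' @param legend an `es_legend`.
#' @param noise_sd standard deviation of the per-study perturbation, in score
#'   units (default 0.8: studies mostly agree within one Likert step).
#' @param coverage probability that a study reports a given (service, class)
#'   pair; 1 = complete matrices.
#' @param seed integer RNG seed.
#' @return List with `studies` (list of `es_study`), `consensus` (an
#'   `es_matrix`), and `latent` (the latent score table).
#' @export
generate_study_matrices <- function(n_studies = 8, services = es_services(),
                                    legend = cglc_legend(), noise_sd = 0.8,
                                    coverage = 1, seed = 1) {
  if (n_studies < 1) abort("need at least one study", "contract")
  S <- nrow(services); K <- nrow(legend)
  codes <- legend_codes(legend)
  with_seed(seed, {
    latent <- matrix(sample(0:5, S * K, replace = TRUE), S, K,
                     dimnames = list(services$code, codes))
    scores <- array(NA_real_, c(n_studies, S, K))
    report <- array(stats::runif(n_studies * S * K) <= coverage,
                    c(n_studies, S, K))
    for (st in seq_len(n_studies)) {
      noisy <- latent + if (noise_sd > 0)
        round(stats::rnorm(S * K, 0, noise_sd)) else 0
      noisy <- pmin(5, pmax(0, noisy))
      m <- matrix(NA_real_, S, K)
      m[report[st, , ]] <- noisy[report[st, , ]]
      scores[st, , ] <- m
    }
    studies <- lapply(seq_len(n_studies), function(st) {
      m <- scores[st, , ]
      idx <- which(!is.na(m), arr.ind = TRUE)
      es_study(sprintf("study_%02d", st),
               services$code[idx[, 1]], codes[idx[, 2]], m[idx],
               location = "synthetic", climate = "arid")
    })
    # ground-truth consensus by direct reduction over the realized array
    cons <- do.call(rbind, lapply(seq_len(S), function(si) {
      do.call(rbind, lapply(seq_len(K), function(ki) {
        v <- scores[, si, ki]
        v <- v[!is.na(v)]
        data.frame(service_code = services$code[si], class_code = codes[ki],
                   min_score = if (length(v)) min(v) else NA_real_,
                   avg_score = if (length(v)) mean(v) else NA_real_,
                   max_score = if (length(v)) max(v) else NA_real_,
                   n_studies = length(v), stringsAsFactors = FALSE)
      }))
    }))
    cons <- cons[order(cons$service_code, cons$class_code), ]
    rownames(cons) <- NULL
    list(studies = studies,
         consensus = es_matrix(cons, services, legend),
         latent = latent)
  })
}

#' A plausible synthetic default ES score matrix
#'
#' The published national score table exists only as a figure, so the package
#' ships this clearly synthetic stand-in: hand-set max scores following the
#' field's usual pattern (forests and wetlands supply most regulating and
#' cultural services strongly; cropland dominates crop provisioning;
#' bare/sparse and built-up supply little), with `avg = max - 1` and
#' `min = max - 2` clipped at 0. Use a transcribed literature matrix for any
#' real assessment.
#'
#' @param services,legend registry and legend.
#' @return An `es_matrix` (attribute `synthetic = TRUE`).
#' @export
synthetic_es_matrix <- function(services = es_services(),
                                legend = cglc_legend()) {
  codes <- legend_codes(legend)
  # rows: services a-j; cols: 20,30,40,50,60,80,90,114,116,124,126
  mx <- rbind(
    a = c(1, 1, 5, 0, 0, 0, 1, 0, 0, 1, 1),  # crop provisioning
    b = c(3, 5, 1, 0, 1, 0, 3, 1, 1, 2, 2),  # grazed biomass
    c = c(2, 0, 1, 0, 0, 0, 1, 5, 5, 4, 4),  # wood supply
    d = c(1, 1, 1, 0, 0, 5, 3, 2, 2, 2, 2),  # water supply
    e = c(2, 2, 1, 0, 0, 1, 3, 5, 5, 4, 4),  # global climate regulation
    f = c(3, 3, 2, 0, 0, 1, 3, 5, 5, 4, 4),  # soil & sediment retention
    g = c(3, 3, 3, 1, 0, 0, 2, 4, 4, 4, 4),  # pollination
    h = c(3, 2, 1, 0, 1, 3, 4, 5, 5, 4, 4),  # nursery population & habitat
    i = c(2, 2, 2, 2, 1, 4, 3, 5, 5, 4, 4),  # recreation-related
    j = c(2, 2, 2, 2, 2, 3, 3, 5, 5, 4, 4))  # spiritual/artistic/symbolic
  df <- expand.grid(class_i = seq_along(codes), service_i = 1:10)
  scores <- data.frame(
    service_code = services$code[df$service_i],
    class_code = codes[df$class_i],
    max_score = mx[cbind(df$service_i, df$class_i)],
    stringsAsFactors = FALSE)
  scores$avg_score <- pmax(0, scores$max_score - 1)
  scores$min_score <- pmax(0, scores$max_score - 2)
  scores$n_studies <- 8L
  scores <- scores[order(scores$service_code, scores$class_code),
                   c("service_code", "class_code", "min_score", "avg_score",
                     "max_score", "n_studies")]
  rownames(scores) <- NULL
  out <- es_matrix(scores, services, legend)
  attr(out, "synthetic") <- TRUE
  out
}
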