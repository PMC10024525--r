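#' The default ecosystem-service registry
#'
#' Ten services, lettered a-j, grouped per the SEEA-EA scheme: four
#' provisioning (crop provisioning, grazed biomass, wood supply, water
#' supply), four regulating & maintenance (global climate regulation, soil
#' and sediment retention, pollination, nursery population and habitat) and
#' two cultural (recreation-related, spiritual/artistic/symbolic).
#'
#' @return A data.frame with columns `code`, `name`, `group`.
#' @export
es_services <- function() {
  data.frame(
    code = letters[1:10],
    name = c("Crop provisioning", "Grazed biomass", "Wood supply",
             "Water supply",
             "Global climate regulation", "Soil and sediment retention",
             "Pollination", "Nursery population and habitat",
             "Recreation-related services",
             "Spiritual, artistic and symbolic services"),
    group = c(rep("provisioning", 4), rep("regulating_maintenance", 4),
              rep("cultural", 2)),
    stringsAsFactors = FALSE)
}

#' Per-study score matrices
#'
#' A study matrix holds one literature study's potential-supply scores on the
#' 0-5 Likert scale, in long (sparse) format: one row per reported
#' (service, class) pair. Pairs a study does not report are simply absent --
#' absence is "not assessed", never score 0.
#'
#' @param study_id study label.
#' @param service_code,class_code,score parallel vectors defining the scored
#'   cells.
#' @param location,climate optional metadata strings.
#' @return An object of class `es_study` (a data.frame).
#' @export
es_study <- function(study_id, service_code, class_code, score,
                     location = "", climate = "") {
  score <- as.numeric(score)
  bad <- which(score < 0 | score > 5 | is.na(score))
  if (length(bad))
    abort(sprintf("study '%s': score out of [0,5] at (service %s, class %s)",
                  study_id, service_code[bad[1]], class_code[bad[1]]),
          "validation")
  if (anyDuplicated(paste(service_code, class_code)))
    abort(sprintf("study '%s': duplicate (service, class) cells", study_id),
          "validation")
  structure(
    data.frame(study_id = study_id, service_code = as.character(service_code),
               class_code = as.integer(class_code), score = score,
               stringsAsFactors = FALSE),
    location = location, climate = climate,
    class = c("es_study", "data.frame"))
}

#' Consensus ES score matrix
#'
#' Scores per (service, class) with `min`, `avg`, `max` variants and the
#' number of contributing studies. Cells no study covers are marked missing
#' (`n_studies = 0`, `NA` scores), never zero: 0 is a meaningful "no
#' potential" score on the 0-5 scale.
#'
#' @param scores data.frame with columns `service_code`, `class_code`,
#'   `min_score`, `avg_score`, `max_score`, `n_studies`, complete over
#'   services x classes.
#' @param services service registry (see [es_services()]).
#' @param legend an `es_legend`.
#' @return An object of class `es_matrix`.
#' @export
es_matrix <- function(scores, services = es_services(),
                      legend = cglc_legend()) {
  covered <- scores$n_studies >= 1
  ok <- with(scores[covered, ],
             min_score >= 0 & min_score <= avg_score &
               avg_score <= max_score & max_score <= 5)
  if (!all(ok))
    abort("matrix violates 0 <= min <= avg <= max <= 5", "validation")
  structure(scores, services = services, legend = legend,
            class = c("es_matrix", "data.frame"))
}

#' @export
print.es_matrix <- function(x, ...) {
  cat(sprintf("<es_matrix> %d services x %d classes, %d cells missing\n",
              length(unique(x$service_code)), length(unique(x$class_code)),
              sum(x$n_studies == 0)))
  invisible(x)
}

#' Build the min/avg/max consensus matrix from literature studies
#'
#' For every (service, class) pair the minimum, arithmetic mean and maximum
#' score across the studies that report that pair, with the count of
#' contributing studies. Pairs no study reports are marked missing.
#'
#' @param studies list of `es_study`.
#' @param services service registry.
#' @param legend an `es_legend` giving the target classes.
#' @return An `es_matrix`.
#' @export
build_consensus_matrix <- function(studies, services = es_services(),
                                   legend = cglc_legend()) {
  if (!length(studies)) abort("need at least one study", "contract")
  all_scores <- data.table::rbindlist(lapply(studies, as.data.frame))
  bad <- all_scores[score < 0 | score > 5]
  if (nrow(bad))
    abort(sprintf("study '%s': score %g out of [0,5] at (service %s, class %d)",
                  bad$study_id[1], bad$score[1], bad$service_code[1],
                  bad$class_code[1]), "validation")
  agg <- all_scores[, .(min_score = min(score), avg_score = mean(score),
                        max_score = max(score), n_studies = .N),
                    by = .(service_code, class_code)]
  full <- data.table::CJ(service_code = services$code,
                         class_code = legend_codes(legend))
  out <- merge(full, agg, by = c("service_code", "class_code"), all.x = TRUE)
  out[is.na(n_studies), n_studies := 0L]
  data.table::setorder(out, service_code, class_code)
  es_matrix(as.data.frame(out), services, legend)
}

#' Crosswalk a study onto the target class and service nomenclature
#'
#' Literature studies use heterogeneous land-cover and service
#' classifications; this reclassifies a study onto the target codes. When
#' several source classes (or services) collapse onto one target, the merged
#' score is the arithmetic mean of the source scores; the provenance of
#' merged cells is attached as attribute `"merged"`.
#'
#' @param study an `es_study` whose labels are source labels.
#' @param class_map named vector: source class label -> target class code.
#' @param service_map named vector: source service label -> target service
#'   code.
#' @return An `es_study` on the target nomenclature.
#' @export
apply_crosswalk <- function(study, class_map, service_map) {
  miss_c <- setdiff(unique(as.character(study$class_code)), names(class_map))
  miss_s <- setdiff(unique(study$service_code), names(service_map))
  if (length(miss_c) || length(miss_s))
    abort(sprintf("unmapped source labels: %s",
                  paste(c(miss_c, miss_s), collapse = ", ")), "mapping")
  dt <- data.table::as.data.table(as.data.frame(study))
  dt[, `:=`(tgt_class = as.integer(class_map[as.character(class_code)]),
            tgt_service = as.character(service_map[service_code]))]
  merged <- dt[, .(score = mean(score), n_src = .N),
               by = .(tgt_service, tgt_class)]
  out <- es_study(study$study_id[1], merged$tgt_service, merged$tgt_class,
                  merged$score,
                  location = attr(study, "location"),
                  climate = attr(study, "climate"))
  attr(out, "merged") <- as.data.frame(merged[n_src > 1])
  out
}

#' Reclassify land cover into a potential-supply score raster
#'
#' The matrix approach reduces ES mapping to a lookup: every pixel receives
#' the score its land-cover class has for the requested service and variant.
#' Nodata pixels stay nodata; classes whose score is missing in the matrix
#' become nodata and their pixel count is reported in a message.
#'
#' @param lc an `es_landcover`.
#' @param matrix an `es_matrix` over the same legend.
#' @param service one-letter service code.
#' @param variant `"min"`, `"avg"` or `"max"`.
#' @return An `es_score_raster`.
#' @export
score_raster <- function(lc, matrix, service, variant = c("max", "avg", "min")) {
  variant <- match.arg(variant)
  mleg <- attr(matrix, "legend")
  if (!legend_equal(lc$legend, mleg))
    abort("raster legend does not match the score matrix classes", "contract")
  sub <- matrix[matrix$service_code == service, ]
  if (!nrow(sub))
    abort(sprintf("service '%s' not in the score matrix", service), "contract")
  col <- paste0(variant, "_score")
  lut <- setNames(sub[[col]], sub$class_code)
  lut[sub$n_studies == 0] <- NA_real_
  vals <- lut[match(lc$values, as.integer(names(lut)))]
  dim(vals) <- c(lc$grid$n_rows, lc$grid$n_cols)   # `matrix` is shadowed here
  n_missing <- sum(lc$values != legend_nodata(lc$legend) & is.na(vals))
  if (n_missing > 0)
    msg_info(sprintf("service %s/%s: %d pixels of classes with missing scores set to nodata",
                     service, variant, n_missing))
  es_score_raster(vals, lc$grid, service, variant, lc$year)
}

#' Score a full (service x variant x year) stack
#'
#' One score raster per combination; with the default registry, variants
#' `{avg, max}` and two years this is the 10 x 2 x 2 = 40-map product of a
#' national assessment.
#'
#' @param series list of `es_landcover` (validated internally when longer
#'   than one).
#' @param matrix an `es_matrix`.
#' @param variants subset of `c("min","avg","max")`.
#' @param years years to score; must be present in the series.
#' @param services service codes; defaults to all in the matrix registry.
#' @return A list of `es_score_raster`.
#' @export
score_stack <- function(series, matrix, variants = c("avg", "max"),
                        years = NULL, services = NULL) {
  if (length(series) >= 2) series <- validate_series(series)
  have <- vapply(series, function(r) r$year, integer(1))
  years <- years %||% have
  if (length(years) == 0) return(list())
  if (!all(years %in% have))
    abort(sprintf("requested year(s) not in series: %s",
                  paste(setdiff(years, have), collapse = ", ")), "contract")
  services <- services %||% attr(matrix, "services")$code
  out <- list()
  for (y in years) {
    lc <- series[[match(y, have)]]
    for (v in variants) for (s in services) {
      r <- score_raster(lc, matrix, s, v)
      out[[sprintf("%s_%s_%d", s, v, y)]] <- r
    }
  }
  out
}

# ---- matrix CSV IO (long format) --------------------------------------

#' Read / write a score matrix CSV
#'
#' Long format, one row per (service, class, variant):
#' `service_code,service_name,class_code,variant,score,n_studies`. Missing
#' cells are rows with empty score and `n_studies = 0`.
#'
#' @param path file path.
#' @param services,legend registry and legend to validate against.
#' @return `read_es_matrix` returns an `es_matrix`.
#' @export
read_es_matrix <- function(path, services = es_services(),
                           legend = cglc_legend()) {
  if (!file.exists(path)) abort(paste("matrix file not found:", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("service_code", "class_code", "variant", "score", "n_studies")
  if (!all(need %in% names(df)))
    abort("matrix CSV lacks required columns", "validation")
  dt <- data.table::as.data.table(df)
  wide <- data.table::dcast(dt, service_code + class_code + n_studies ~ variant,
                            value.var = "score")
  for (v in c("min", "avg", "max"))
    if (!v %in% names(wide)) wide[, (v) := NA_real_]
  data.table::setnames(wide, c("min", "avg", "max"),
                       c("min_score", "avg_score", "max_score"))
  data.table::setorder(wide, service_code, class_code)
  es_matrix(as.data.frame(wide), services, legend)
}

#' @rdname read_es_matrix
#' @param matrix an `es_matrix`.
#' @export
write_es_matrix <- function(matrix, path) {
  services <- attr(matrix, "services")
  dt <- data.table::as.data.table(as.data.frame(matrix))
  long <- data.table::melt(dt,
    id.vars = c("service_code", "class_code", "n_studies"),
    measure.vars = c("min_score", "avg_score", "max_score"),
    variable.name = "variant", value.name = "score")
  long[, variant := sub("_score$", "", variant)]
  long[, service_name := services$name[match(service_code, services$code)]]
  data.table::setcolorder(long, c("service_code", "service_name",
                                  "class_code", "variant", "score",
                                  "n_studies"))
  data.table::setorder(long, service_code, class_code, variant)
  utils::write.csv(as.data.frame(long), path, row.names = FALSE, na = "")
  invisible(path)
}
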