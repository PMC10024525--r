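#' Land-cover legends
#'
#' A legend maps integer class codes to class names and fixes the nodata
#' sentinel. Codes must be unique and distinct from the nodata code.
#'
#' @param class_code integer vector of unique class codes.
#' @param class_name character vector of class names, same length.
#' @param nodata integer nodata sentinel (default 0, the CGLC convention).
#' @return An object of class `es_legend`: a data.frame with columns
#'   `class_code`, `class_name` and attribute `nodata`.
#' @export
es_legend <- function(class_code, class_name, nodata = 0L) {
  class_code <- as.integer(class_code)
  if (anyDuplicated(class_code))
    abort("legend class codes must be unique", "validation")
  if (as.integer(nodata) %in% class_code)
    abort("nodata code must not be a legend class code", "validation")
  if (length(class_code) != length(class_name))
    abort("class_code and class_name lengths differ", "contract")
  structure(
    data.frame(class_code = class_code, class_name = as.character(class_name),
               stringsAsFactors = FALSE),
    nodata = as.integer(nodata),
    class = c("es_legend", "data.frame"))
}

legend_nodata <- function(legend) attr(legend, "nodata")
legend_codes  <- function(legend) legend$class_code

legend_equal <- function(a, b) {
  identical(legend_codes(a), legend_codes(b)) &&
    legend_nodata(a) == legend_nodata(b)
}

#' The 11-class CGLC-style legend
#'
#' Default legend for Copernicus Global Land Cover style maps of an arid
#' East-African landscape: the discrete-classification codes of the 11 classes
#' present (shrubs, herbaceous, cropland, built-up, bare/sparse, water,
#' herbaceous wetland, and four forest classes), with nodata 0.
#'
#' @return An `es_legend` with 11 entries.
#' @export
cglc_legend <- function() {
  es_legend(
    class_code = c(20L, 30L, 40L, 50L, 60L, 80L, 90L, 114L, 116L, 124L, 126L),
    class_name = c(
      "Shrubs",
      "Herbaceous vegetation",
      "Cultivated and managed vegetation/agriculture",
      "Urban/built up",
      "Bare/sparse vegetation",
      "Permanent water bodies",
      "Herbaceous wetland",
      "Closed forest, deciduous broad leaf",
      "Closed forest, other",
      "Open forest, deciduous broad leaf",
      "Open forest, other"),
    nodata = 0L)
}

#' Read / write a legend CSV
#'
#' Format: a CSV with header `class_code,class_name`.
#'
#' @param path file path.
#' @param nodata nodata code to attach on read.
#' @return `read_legend` returns an `es_legend`; `write_legend` returns the
#'   path invisibly.
#' @export
read_legend <- function(path, nodata = 0L) {
  if (!file.exists(path)) abort(paste("legend file not found:", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class_code", "class_name") %in% names(df)))
    abort("legend CSV must have columns class_code,class_name", "validation")
  es_legend(df$class_code, df$class_name, nodata = nodata)
}

#' @rdname read_legend
#' @param legend an `es_legend`.
#' @export
write_legend <- function(legend, path) {
  utils::write.csv(as.data.frame(legend)[, c("class_code", "class_name")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
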