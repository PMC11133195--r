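#' Canonical functional ecological areas
#'
#' The seven broad habitat categories used as connectivity source/target
#' classes: forest, shrubland, grassland or paramo vegetation, agroforestry
#' mosaics, crops, pastures and sugarcane. The hydrological network can be
#' carried as an additional traversable area (see [default_affinity()]);
#' it is not a connectivity target by default.
#'
#' @return character vector of length 7.
#' @export
functional_areas <- function() {
  c("forest", "shrubland", "grassland_paramo", "agroforestry_mosaic",
    "crops", "pastures", "sugarcane")
}

lc_typologies <- function() {
  c("forest_seminatural", "agricultural", "water", "built", "other")
}

#' Build a land-cover legend
#'
#' A legend maps integer class codes to names, broad typologies, report
#' roll-up groups, the habitat categories used by the Shannon metric, the
#' functional ecological areas used by the connectivity model, and barrier
#' flags for anthropogenic barriers (urban areas, infrastructure).
#'
#' @param code integer class codes (unique, none equal to `nodata`).
#' @param name class names.
#' @param typology one of `forest_seminatural`, `agricultural`, `water`,
#'   `built`, `other` per class.
#' @param reclass_group roll-up group label per class (report rows).
#' @param habitat_category habitat grouping for the Shannon metric, or `NA`
#'   for classes excluded from it.
#' @param functional_area functional ecological area per class, or `NA`.
#'   Values must come from `area_set`.
#' @param barrier_flag logical; `TRUE` for anthropogenic barrier classes.
#' @param nodata integer code reserved for missing cells.
#' @param area_set allowed functional-area labels; defaults to the seven
#'   canonical areas plus `"water"`.
#' @return a `data.frame` of class `lm_legend` with attribute `nodata`.
#' @export
legend_table <- function(code, name, typology, reclass_group = name,
                         habitat_category = NA_character_,
                         functional_area = NA_character_,
                         barrier_flag = FALSE,
                         nodata = -9999L,
                         area_set = c(functional_areas(), "water")) {
  code <- as.integer(code)
  n <- length(code)
  lg <- data.frame(
    code = code,
    name = as.character(name),
    typology = as.character(typology),
    reclass_group = as.character(rep_len(reclass_group, n)),
    habitat_category = as.character(rep_len(habitat_category, n)),
    functional_area = as.character(rep_len(functional_area, n)),
    barrier_flag = as.logical(rep_len(barrier_flag, n)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(lg$code))
    validation_error(sprintf(
      "duplicate legend codes: %s",
      paste(unique(lg$code[duplicated(lg$code)]), collapse = ", ")))
  if (any(lg$code == nodata))
    validation_error("nodata code must not appear among legend entries")
  bad_typ <- setdiff(unique(lg$typology), lc_typologies())
  if (length(bad_typ))
    validation_error(sprintf("unknown typology values: %s",
                             paste(bad_typ, collapse = ", ")))
  fa <- lg$functional_area[!is.na(lg$functional_area)]
  bad_fa <- setdiff(unique(fa), area_set)
  if (length(bad_fa))
    validation_error(sprintf("functional_area values outside configured set: %s",
                             paste(bad_fa, collapse = ", ")))
  attr(lg, "nodata") <- as.integer(nodata)
  class(lg) <- c("lm_legend", "data.frame")
  lg
}

#' Read / write a legend CSV
#'
#' Columns: `code,name,typology,reclass_group,habitat_category,functional_area,barrier_flag`.
#'
#' @param path file path.
#' @param nodata nodata code (not stored in the CSV).
#' @param area_set allowed functional-area labels.
#' @return `read_legend()` returns an `lm_legend`; `write_legend()` returns
#'   `path` invisibly.
#' @export
read_legend <- function(path, nodata = -9999L,
                        area_set = c(functional_areas(), "water")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "typology", "reclass_group", "habitat_category",
            "functional_area", "barrier_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    validation_error(sprintf("legend CSV missing columns: %s",
                             paste(miss, collapse = ", ")))
  df$habitat_category[df$habitat_category %in% c("", "NA")] <- NA_character_
  df$functional_area[df$functional_area %in% c("", "NA")] <- NA_character_
  legend_table(df$code, df$name, df$typology, df$reclass_group,
               df$habitat_category, df$functional_area,
               as.logical(df$barrier_flag), nodata = nodata,
               area_set = area_set)
}

#' @rdname read_legend
#' @param legend an `lm_legend`.
#' @export
write_legend <- function(legend, path) {
  utils::write.csv(as.data.frame(legend), path, row.names = FALSE, na = "")
  invisible(path)
}
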