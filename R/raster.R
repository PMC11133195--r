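#' Construct a categorical land-cover raster
#'
#' A thin wrapper around an integer matrix with the planar georeferencing the
#' pipeline needs: square cells of `cell_size` metres, `origin` at the
#' top-left corner, row-major storage (row 1 = northernmost row). No
#' geographic reprojection is performed anywhere in the package; coordinates
#' are assumed planar and equal-area.
#'
#' @param grid integer matrix of class codes.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric `c(x, y)` of the top-left corner.
#' @param nodata integer nodata code.
#' @param legend optional `lm_legend`; when given, every non-nodata code in
#'   `grid` must appear in it.
#' @return an `lm_raster` object.
#' @export
lc_raster <- function(grid, cell_size, origin = c(0, 0), nodata = -9999L,
                      legend = NULL) {
  if (!is.matrix(grid) || nrow(grid) < 1 || ncol(grid) < 1)
    invalid_argument("grid must be a matrix with at least one cell")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    invalid_argument("cell_size must be a single positive number (metres)")
  storage.mode(grid) <- "integer"
  r <- structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.integer(nodata)),
    class = "lm_raster"
  )
  if (!is.null(legend)) validate_raster(r, legend)
  r
}

#' @export
print.lm_raster <- function(x, ...) {
  cat(sprintf("lm_raster: %d x %d cells, %.0f m cells, nodata = %d\n",
              nrow(x$grid), ncol(x$grid), x$cell_size, x$nodata))
  invisible(x)
}

#' Validate raster codes against a legend
#'
#' @param raster an `lm_raster`.
#' @param legend an `lm_legend`.
#' @return the raster, invisibly; errors list every offending code at once.
#' @export
validate_raster <- function(raster, legend) {
  codes <- unique(as.vector(raster$grid))
  codes <- codes[codes != raster$nodata]
  bad <- setdiff(codes, legend$code)
  if (length(bad))
    validation_error(sprintf("raster codes missing from legend: %s",
                             paste(sort(bad), collapse = ", ")))
  invisible(raster)
}

# cell area in hectares
cell_area_ha <- function(raster) raster$cell_size^2 / 1e4

# cell-centre coordinates; returns list(x = by column, y = by row)
cell_centers <- function(raster) {
  cs <- raster$cell_size
  list(
    x = raster$origin[1] + (seq_len(ncol(raster$grid)) - 0.5) * cs,
    y = raster$origin[2] - (seq_len(nrow(raster$grid)) - 0.5) * cs
  )
}

#' Reclassify a raster
#'
#' @param raster an `lm_raster`.
#' @param mapping named integer vector: `mapping[as.character(code)]` is the
#'   output code. Must cover every non-nodata code present.
#' @return reclassified `lm_raster`; nodata cells preserved.
#' @export
reclassify <- function(raster, mapping) {
  g <- raster$grid
  codes <- unique(as.vector(g))
  codes <- codes[codes != raster$nodata]
  unmapped <- codes[!as.character(codes) %in% names(mapping)]
  if (length(unmapped))
    validation_error(sprintf("reclassify: unmapped codes present: %s",
                             paste(sort(unmapped), collapse = ", ")))
  out <- g
  keep <- g != raster$nodata
  out[keep] <- as.integer(mapping[as.character(g[keep])])
  lc_raster(out, raster$cell_size, raster$origin, raster$nodata)
}

#' Area accounting from per-class areas
#'
#' Builds the area/percent report (per class and per roll-up group) from
#' already-known class areas — the arithmetic behind printed land-cover
#' distribution tables. Percents are of the grand total; group rows are exact
#' sums of their members.
#'
#' @param areas_ha named numeric vector of class areas in hectares; names are
#'   class codes present in `legend`.
#' @param legend an `lm_legend` supplying names, typologies and roll-up groups.
#' @param percent_base denominator for the percent column; defaults to the
#'   sum of the class areas. Published tables sometimes carry a separate
#'   printed study-area total as their percent base; pass it here to
#'   reproduce their percents.
#' @return an `lm_area_table`: data.frame with columns `typology, land_cover,
#'   reclass, area_ha, percent` and attributes `groups` (per-group sums),
#'   `total_ha` (sum of class areas) and `percent_base`.
#' @export
area_table <- function(areas_ha, legend, percent_base = NULL) {
  if (any(areas_ha < 0)) invalid_argument("class areas must be non-negative")
  codes <- as.integer(names(areas_ha))
  bad <- setdiff(codes, legend$code)
  if (length(bad))
    validation_error(sprintf("areas reference codes missing from legend: %s",
                             paste(bad, collapse = ", ")))
  i <- match(codes, legend$code)
  tab <- data.frame(
    code = codes,
    typology = legend$typology[i],
    land_cover = legend$name[i],
    reclass = legend$reclass_group[i],
    area_ha = as.numeric(areas_ha),
    stringsAsFactors = FALSE
  )
  total <- sum(tab$area_ha)
  if (total <= 0) empty_result("no valid area to account")
  base <- percent_base %||% total
  tab$percent <- 100 * tab$area_ha / base
  grp <- stats::aggregate(area_ha ~ reclass, tab, sum)
  grp$percent <- 100 * grp$area_ha / base
  structure(tab, groups = grp, total_ha = total, percent_base = base,
            class = c("lm_area_table", "data.frame"))
}

#' Summarise raster areas per class and group
#'
#' Area per class = valid cell count x cell area; percent of total valid area.
#'
#' @param raster an `lm_raster`.
#' @param legend an `lm_legend`; the raster is validated against it.
#' @return an `lm_area_table` (see [area_table()]).
#' @export
summarize_areas <- function(raster, legend) {
  validate_raster(raster, legend)
  v <- as.vector(raster$grid)
  v <- v[v != raster$nodata]
  if (!length(v)) empty_result("raster contains no valid cells")
  counts <- table(v)
  areas <- as.numeric(counts) * cell_area_ha(raster)
  names(areas) <- names(counts)
  area_table(areas, legend)
}

#' Group roll-up of an area table
#'
#' @param tab an `lm_area_table`.
#' @return data.frame `reclass, area_ha, percent` (exact member sums).
#' @export
area_groups <- function(tab) attr(tab, "groups")

#' @export
print.lm_area_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$area_ha <- round_half_up(df$area_ha, 2)
  df$percent <- round_half_up(df$percent, 1)
  print(df, row.names = FALSE)
  cat(sprintf("Total: %s ha\n", format(attr(x, "total_ha"), big.mark = ",")))
  invisible(x)
}

#' Write an area table as CSV
#'
#' Columns `typology,land_cover,reclass,area_ha,percent`; percents rounded to
#' one decimal (half-up), areas to 2 decimals, matching report formatting.
#'
#' @param tab an `lm_area_table`.
#' @param path output path.
#' @export
write_area_table <- function(tab, path) {
  df <- as.data.frame(tab)[, c("typology", "land_cover", "reclass",
                               "area_ha", "percent")]
  df$area_ha <- round_half_up(df$area_ha, 2)
  df$percent <- round_half_up(df$percent, 1)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
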