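#' Read an ESRI ASCII grid
#'
#' Single-band integer grids in the plain-text Arc/Info ASCII format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed by
#' row-major values, first row northernmost).
#'
#' @param path file path.
#' @param nodata optional override of the file's `NODATA_value`.
#' @return an `lm_raster`.
#' @export
read_ascii_grid <- function(path, nodata = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    validation_error(sprintf("ASCII grid header missing: %s",
                             paste(miss, collapse = ", ")))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    validation_error(sprintf("ASCII grid: expected %d values, found %d",
                             nr * nc, length(vals)))
  grid <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  nd <- as.integer(nodata %||% hdr$nodata_value %||% -9999)
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  lc_raster(grid, hdr$cellsize, origin = c(xll, yll + nr * hdr$cellsize),
            nodata = nd)
}

#' Write an ESRI ASCII grid
#'
#' @param raster an `lm_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2] - nrow(g) * raster$cell_size),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %d", raster$nodata)
  )
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
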