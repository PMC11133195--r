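#' Number of equal-area analysis units needed to tile an area
#'
#' @param extent_area_ha total area to be tiled (ha).
#' @param cell_area_ha area of one analysis unit (ha).
#' @return integer count `ceiling(extent_area_ha / cell_area_ha)` — the
#'   whole-cell-equivalent number of units when edge cells are clipped.
#' @export
n_analysis_units <- function(extent_area_ha, cell_area_ha) {
  if (extent_area_ha <= 0 || cell_area_ha <= 0)
    invalid_argument("areas must be positive")
  as.integer(ceiling(extent_area_ha / cell_area_ha - 1e-9))
}

hex_side_from_area <- function(area_m2) sqrt(2 * area_m2 / (3 * sqrt(3)))

hex_vertices <- function(cx, cy, s, orientation) {
  ang <- if (orientation == "flat_top") (0:5) * pi / 3 else (0:5) * pi / 3 + pi / 6
  cbind(cx + s * cos(ang), cy + s * sin(ang))
}

#' Build an equal-area hexagon grid over a rectangular extent
#'
#' Hexagons are laid out on a regular lattice covering the extent; boundary
#' hexagons are clipped to the extent rectangle. Interior (unclipped) cells
#' all share `cell_area` exactly up to floating point. Generation is fully
#' deterministic: identical extent/cell_area/orientation give identical
#' geometry, with `hex_id` assigned row-wise from the top-left.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in map units (metres).
#' @param cell_area hexagon area in hectares (> 0).
#' @param orientation `"flat_top"` (default) or `"pointy_top"`.
#' @return an `lm_hexgrid`: data.frame with `hex_id, cx, cy, area_ha`
#'   (clipped), `full_area_ha`, `clipped` flag; attributes `vertices` (list of
#'   rings, clipped), `side` (m), `extent`, `cell_area`, `orientation` and
#'   `units_equivalent` (clipped total area / cell_area, rounded up).
#' @export
build_hex_grid <- function(extent, cell_area, orientation = c("flat_top", "pointy_top")) {
  orientation <- match.arg(orientation)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    invalid_argument("extent must be c(xmin, xmax, ymin, ymax) with positive width and height")
  if (!is.numeric(cell_area) || cell_area <= 0)
    invalid_argument("cell_area must be positive (ha)")
  s <- hex_side_from_area(cell_area * 1e4)
  xmin <- extent[1]; xmax <- extent[2]; ymin <- extent[3]; ymax <- extent[4]

  if (orientation == "flat_top") {
    dx <- 1.5 * s; dy <- sqrt(3) * s
    qs <- seq(floor((xmin - s) / dx), ceiling((xmax + s) / dx))
    rs <- seq(floor((ymin - s) / dy) - 1, ceiling((ymax + s) / dy) + 1)
    centers <- expand.grid(q = qs, r = rs)
    centers$cx <- xmin + centers$q * dx
    centers$cy <- ymin + centers$r * dy + ifelse(centers$q %% 2 != 0, dy / 2, 0)
  } else {
    dyp <- 1.5 * s; dxp <- sqrt(3) * s
    rs <- seq(floor((ymin - s) / dyp), ceiling((ymax + s) / dyp))
    qs <- seq(floor((xmin - s) / dxp) - 1, ceiling((xmax + s) / dxp) + 1)
    centers <- expand.grid(q = qs, r = rs)
    centers$cy <- ymin + centers$r * dyp
    centers$cx <- xmin + centers$q * dxp + ifelse(centers$r %% 2 != 0, dxp / 2, 0)
  }

  rings <- vector("list", nrow(centers))
  area <- full <- numeric(nrow(centers))
  keep <- logical(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    v <- hex_vertices(centers$cx[i], centers$cy[i], s, orientation)
    clipped <- clip_polygon_rect(v, xmin, xmax, ymin, ymax)
    a <- if (nrow(clipped) >= 3) polygon_area(clipped) else 0
    if (a > 1e-9) {
      keep[i] <- TRUE
      rings[[i]] <- clipped
      area[i] <- a / 1e4
      full[i] <- polygon_area(v) / 1e4
    }
  }
  if (!any(keep)) empty_result("no hexagon intersects the extent")
  centers <- centers[keep, , drop = FALSE]
  rings <- rings[keep]; area <- area[keep]; full <- full[keep]
  ord <- order(-centers$cy, centers$cx)
  cells <- data.frame(
    hex_id = seq_along(ord),
    cx = centers$cx[ord], cy = centers$cy[ord],
    area_ha = area[ord], full_area_ha = full[ord],
    clipped = abs(area[ord] - full[ord]) > 1e-6 * full[ord]
  )
  structure(cells,
            vertices = rings[ord], side = s, extent = extent,
            cell_area = cell_area, orientation = orientation,
            units_equivalent = n_analysis_units(sum(area), cell_area),
            class = c("lm_hexgrid", "data.frame"))
}

#' @export
print.lm_hexgrid <- function(x, ...) {
  cat(sprintf("lm_hexgrid: %d cells of %.0f ha (%s), %d unit-equivalents\n",
              nrow(x), attr(x, "cell_area"), attr(x, "orientation"),
              attr(x, "units_equivalent")))
  invisible(x)
}

# nearest hexagon centre per point; exact point-in-hexagon for a regular
# tiling (the tiling is the Voronoi diagram of its centres); ties go to the
# lower hex_id because which.min takes the first minimum in id order.
assign_to_hex <- function(grid, px, py) {
  n <- length(px)
  out <- integer(n)
  cx <- grid$cx; cy <- grid$cy
  chunk <- max(1L, floor(5e6 / length(cx)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(px[idx], cx, "-")^2 + outer(py[idx], cy, "-")^2
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Per-hexagon land-cover composition
#'
#' Assigns every raster cell to the hexagon containing its centre and tallies
#' class proportions per hexagon over valid (non-nodata) cells. Hexagons whose
#' valid coverage falls below `min_valid_fraction` of their full area are
#' flagged excluded; retained rows sum to one.
#'
#' @param raster an `lm_raster` in the same planar frame as `grid`.
#' @param grid an `lm_hexgrid`.
#' @param min_valid_fraction minimum valid-coverage fraction to retain a
#'   hexagon (default 0.5).
#' @return an `lm_composition`: list with `P` (hexagon x class proportion
#'   matrix, rownames = hex_id, colnames = class code), `valid_fraction`,
#'   `excluded` (logical), `n_valid` (cells), `cell_area_ha`.
#' @export
compute_composition <- function(raster, grid, min_valid_fraction = 0.5) {
  cc <- cell_centers(raster)
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  codes <- as.vector(raster$grid)
  ext <- attr(grid, "extent")
  inside <- px >= ext[1] & px <= ext[2] & py >= ext[3] & py <= ext[4]
  if (!any(inside)) empty_result("raster and hexagon grid do not overlap")
  hex <- rep(NA_integer_, length(px))
  hex[inside] <- assign_to_hex(grid, px[inside], py[inside])

  valid <- inside & codes != raster$nodata
  cls <- sort(unique(codes[valid]))
  nh <- nrow(grid)
  counts <- matrix(0L, nh, length(cls), dimnames = list(grid$hex_id, cls))
  if (any(valid)) {
    tb <- table(factor(hex[valid], levels = seq_len(nh)),
                factor(codes[valid], levels = cls))
    counts <- matrix(as.integer(tb), nh, length(cls),
                     dimnames = list(grid$hex_id, cls))
  }
  n_valid <- rowSums(counts)
  ca <- cell_area_ha(raster)
  valid_fraction <- pmin(1, n_valid * ca / grid$full_area_ha)
  excluded <- valid_fraction < min_valid_fraction
  P <- counts / ifelse(n_valid > 0, n_valid, NA_real_)
  P[n_valid == 0, ] <- NA_real_
  structure(list(P = P, valid_fraction = valid_fraction,
                 excluded = excluded, n_valid = n_valid,
                 cell_area_ha = ca, hex_id = grid$hex_id),
            class = "lm_composition")
}

#' @export
print.lm_composition <- function(x, ...) {
  cat(sprintf("lm_composition: %d hexagons x %d classes, %d retained\n",
              nrow(x$P), ncol(x$P), sum(!x$excluded)))
  invisible(x)
}

#' Write a hexagon grid (with optional per-hexagon properties) as GeoJSON
#'
#' @param grid an `lm_hexgrid`.
#' @param path output path.
#' @param properties optional data.frame of extra per-hexagon fields, one row
#'   per hexagon in `hex_id` order.
#' @return `path`, invisibly.
#' @export
write_hex_geojson <- function(grid, path, properties = NULL) {
  rings <- attr(grid, "vertices")
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    ring <- rings[[i]]
    ring <- rbind(ring, ring[1, ])
    props <- list(hex_id = grid$hex_id[i])
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read hexagon properties back from a GeoJSON written by [write_hex_geojson()]
#'
#' @param path GeoJSON path.
#' @return data.frame of feature properties (one row per hexagon).
#' @export
read_hex_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- lapply(gj$features, function(f) as.data.frame(f$properties))
  do.call(rbind, props)
}
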