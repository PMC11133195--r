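#' Affinity matrix over functional ecological areas
#'
#' @param m square numeric matrix with identical row/column names (the
#'   configured functional-area set), entries in (0, 1], unit diagonal.
#' @param symmetric require symmetry (default TRUE).
#' @return validated affinity matrix of class `lm_affinity`.
#' @export
affinity_matrix <- function(m, symmetric = TRUE) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    invalid_argument("affinity must be a square matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    validation_error("affinity matrix needs identical row and column names")
  if (any(m <= 0) || any(m > 1))
    validation_error("affinity entries must lie in (0, 1]")
  if (any(abs(diag(m) - 1) > 1e-12))
    validation_error("affinity diagonal must be 1")
  if (symmetric && any(abs(m - t(m)) > 1e-12))
    validation_error("affinity matrix is not symmetric")
  class(m) <- c("lm_affinity", class(m))
  m
}

#' Default affinity matrix
#'
#' Placeholder coefficients over the seven canonical functional areas plus
#' the hydrological network (`water`, affinity 0.8 to forest). The study
#' coefficients were expert-derived and unpublished; these defaults encode
#' the usual ordering (structurally similar habitats high, intensive covers
#' low) and are meant to be replaced by user-supplied values.
#'
#' @return an `lm_affinity` (8 x 8).
#' @export
default_affinity <- function() {
  areas <- c(functional_areas(), "water")
  m <- matrix(1, 8, 8, dimnames = list(areas, areas))
  set <- function(a, b, v) { m[a, b] <<- v; m[b, a] <<- v }
  set("forest", "shrubland", 0.8)
  set("forest", "grassland_paramo", 0.6)
  set("forest", "agroforestry_mosaic", 0.6)
  set("forest", "crops", 0.3)
  set("forest", "pastures", 0.4)
  set("forest", "sugarcane", 0.1)
  set("shrubland", "grassland_paramo", 0.8)
  set("shrubland", "agroforestry_mosaic", 0.6)
  set("shrubland", "crops", 0.3)
  set("shrubland", "pastures", 0.4)
  set("shrubland", "sugarcane", 0.1)
  set("grassland_paramo", "agroforestry_mosaic", 0.5)
  set("grassland_paramo", "crops", 0.3)
  set("grassland_paramo", "pastures", 0.5)
  set("grassland_paramo", "sugarcane", 0.1)
  set("agroforestry_mosaic", "crops", 0.7)
  set("agroforestry_mosaic", "pastures", 0.6)
  set("agroforestry_mosaic", "sugarcane", 0.2)
  set("crops", "pastures", 0.6)
  set("crops", "sugarcane", 0.4)
  set("pastures", "sugarcane", 0.3)
  set("water", "forest", 0.8)
  set("water", "shrubland", 0.6)
  set("water", "grassland_paramo", 0.5)
  set("water", "agroforestry_mosaic", 0.5)
  set("water", "crops", 0.3)
  set("water", "pastures", 0.4)
  set("water", "sugarcane", 0.2)
  affinity_matrix(m)
}

#' Read / write an affinity matrix CSV (row/column headers = area names)
#'
#' @param path file path.
#' @param symmetric require symmetry on read.
#' @export
read_affinity <- function(path, symmetric = TRUE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    validation_error(sprintf(
      "affinity matrix must be square over named areas; got %d x %d (%s)",
      nrow(m), ncol(m), paste(rownames(m), collapse = ", ")))
  affinity_matrix(m, symmetric = symmetric)
}

#' @rdname read_affinity
#' @param affinity an `lm_affinity`.
#' @export
write_affinity <- function(affinity, path) {
  utils::write.csv(unclass(affinity), path)
  invisible(path)
}

#' Barrier specification
#'
#' @param class integer barrier class codes.
#' @param impact additive friction contributed to every cell within the halo
#'   (>= 0, cost units).
#' @param halo_m halo radius in metres (>= 0; 0 = the barrier cell only).
#' @param impermeable logical; impermeable cells are removed from traversal.
#' @return data.frame of class `lm_barriers`.
#' @export
barrier_spec <- function(class, impact = 0, halo_m = 0, impermeable = FALSE) {
  n <- length(class)
  b <- data.frame(class = as.integer(class),
                  impact = as.numeric(rep_len(impact, n)),
                  halo_m = as.numeric(rep_len(halo_m, n)),
                  impermeable = as.logical(rep_len(impermeable, n)))
  if (any(b$impact < 0) || any(b$halo_m < 0))
    validation_error("barrier impact and halo_m must be non-negative")
  class(b) <- c("lm_barriers", "data.frame")
  b
}

#' Read / write a barrier spec CSV (`class,impact,halo_m,impermeable`)
#' @param path file path.
#' @export
read_barriers <- function(path) {
  df <- utils::read.csv(path)
  barrier_spec(df$class, df$impact, df$halo_m, as.logical(df$impermeable))
}

#' @rdname read_barriers
#' @param barriers an `lm_barriers`.
#' @export
write_barriers <- function(barriers, path) {
  utils::write.csv(as.data.frame(barriers), path, row.names = FALSE)
  invisible(path)
}

# additive halo field and impermeable mask; independent of the target area,
# so computed once and reused across the m per-area friction surfaces
barrier_field <- function(raster, legend, barriers) {
  g <- raster$grid
  nr <- nrow(g); nc <- ncol(g)
  add <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  if (is.null(barriers) || nrow(barriers) == 0)
    return(list(add = add, mask = mask))
  cs <- raster$cell_size
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (i in seq_len(nrow(barriers))) {
    hit <- which(g == barriers$class[i], arr.ind = TRUE)
    if (!nrow(hit)) next
    if (barriers$impermeable[i]) mask[hit] <- TRUE
    imp <- barriers$impact[i]
    if (imp > 0) {
      rad <- barriers$halo_m[i] / cs  # radius in cell lengths
      within <- matrix(FALSE, nr, nc)
      for (k in seq_len(nrow(hit))) {
        d2 <- (rows - hit[k, 1])^2 + (cols - hit[k, 2])^2
        within <- within | d2 <= rad^2 + 1e-9
      }
      add <- add + imp * within
    }
  }
  list(add = add, mask = mask)
}

#' Build a friction surface for one target functional area
#'
#' Per-cell traversal cost `base_cost / affinity(area(cell), target_area)`
#' plus the additive impact of every barrier halo covering the cell;
#' impermeable barrier cells and nodata cells are masked. Barrier classes
#' with no functional area travel at the worst (minimum) affinity.
#'
#' @param raster an `lm_raster`.
#' @param legend an `lm_legend`; every non-nodata class must carry a
#'   functional area or a barrier flag.
#' @param affinity an `lm_affinity` whose names include every functional area
#'   used and `target_area`.
#' @param barriers an `lm_barriers` (or NULL).
#' @param target_area name of the target functional area.
#' @param base_cost base traversal cost per cell length (default 1).
#' @param .barrier_field precomputed [barrier_field] (internal reuse).
#' @return an `lm_friction`: list with `cost` (matrix, NA on mask), `mask`,
#'   `cell_size`.
#' @export
build_friction <- function(raster, legend, affinity, barriers = NULL,
                           target_area, base_cost = 1,
                           .barrier_field = NULL) {
  g <- raster$grid
  if (!target_area %in% rownames(affinity))
    invalid_argument(sprintf("target_area '%s' not in affinity matrix", target_area))
  codes <- unique(as.vector(g)); codes <- codes[codes != raster$nodata]
  li <- match(codes, legend$code)
  if (anyNA(li))
    validation_error(sprintf("raster codes missing from legend: %s",
                             paste(codes[is.na(li)], collapse = ", ")))
  fa <- legend$functional_area[li]
  bf <- legend$barrier_flag[li]
  orphan <- codes[is.na(fa) & !bf]
  if (length(orphan))
    validation_error(sprintf(
      "classes lacking both functional_area and barrier_flag: %s",
      paste(orphan, collapse = ", ")))
  aff <- rep(min(affinity), length(fa))  # barrier-only classes: worst affinity
  aff[!is.na(fa)] <- affinity[fa[!is.na(fa)], target_area]
  per_class <- base_cost / aff
  names(per_class) <- codes

  cost <- matrix(NA_real_, nrow(g), ncol(g))
  keep <- g != raster$nodata
  cost[keep] <- per_class[as.character(g[keep])]
  bfld <- .barrier_field %||% barrier_field(raster, legend, barriers)
  cost <- cost + bfld$add
  mask <- bfld$mask | !keep
  cost[mask] <- NA_real_
  structure(list(cost = cost, mask = mask, cell_size = raster$cell_size),
            class = "lm_friction")
}

# lattice edge list for a friction surface; weight = mean(friction) * step
lattice_edges <- function(cost, connectivity) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- matrix(seq_len(nr * nc), nr, nc)
  e_from <- integer(0); e_to <- integer(0); e_w <- numeric(0)
  add_dir <- function(dr, dc, step) {
    rows1 <- if (dr >= 0) seq_len(nr - dr) else seq(1 - dr, nr)
    cols1 <- seq_len(nc - dc)
    # flatten: an index matrix with exactly 2 columns would otherwise be
    # read as (row, col) coordinate pairs
    a <- as.vector(id[rows1, cols1, drop = FALSE])
    b <- as.vector(id[rows1 + dr, cols1 + dc, drop = FALSE])
    w <- (cost[a] + cost[b]) / 2 * step
    ok <- !is.na(w)
    e_from <<- c(e_from, a[ok]); e_to <<- c(e_to, b[ok]); e_w <<- c(e_w, w[ok])
  }
  add_dir(1, 0, 1)   # down
  add_dir(0, 1, 1)   # right
  if (connectivity == 8) {
    add_dir(1, 1, sqrt(2))   # down-right
    add_dir(-1, 1, sqrt(2))  # up-right
  }
  list(from = e_from, to = e_to, w = e_w, n = nr * nc)
}

#' Accumulated least-cost distance from source cells
#'
#' Exact Dijkstra shortest-path costs on the 4- or 8-connected cell graph,
#' with edge weight = mean friction of the two endpoint cells times step
#' length (1 within rows/columns, sqrt(2) diagonally, in cell lengths).
#' A zero-cost virtual super-source ties all sources together so one sweep
#' yields the minimum over sources.
#'
#' @param friction an `lm_friction`.
#' @param sources integer cell indices (column-major into the cost matrix) or
#'   a logical matrix of the same shape.
#' @param connectivity 4 or 8 (default 8).
#' @param Xt theoretical maximum cost; defaults to
#'   [theoretical_max_cost()]. Costs are clamped to `Xt`; unreachable and
#'   masked cells carry `Xt`.
#' @return an `lm_cost`: list with `X` (matrix of accumulated costs), `Xt`,
#'   `sources`.
#' @export
accumulate_cost <- function(friction, sources, connectivity = 8, Xt = NULL) {
  if (!connectivity %in% c(4, 8))
    invalid_argument("connectivity must be 4 or 8")
  cost <- friction$cost
  if (is.matrix(sources)) sources <- which(sources)
  sources <- as.integer(sources)
  if (!length(sources)) invalid_argument("at least one source cell required")
  sources <- sources[!friction$mask[sources]]
  if (!length(sources)) empty_result("all source cells are masked")
  Xt <- Xt %||% theoretical_max_cost(friction)

  ed <- lattice_edges(cost, connectivity)
  super <- ed$n + 1L
  gr <- igraph::make_empty_graph(n = super, directed = FALSE)
  gr <- igraph::add_edges(
    gr,
    rbind(c(ed$from, rep(super, length(sources))),
          c(ed$to, sources)),
    weight = c(ed$w, rep(0, length(sources)))
  )
  d <- igraph::distances(gr, v = super, algorithm = "dijkstra")[1, ]
  X <- matrix(d[seq_len(ed$n)], nrow(cost), ncol(cost))
  X[!is.finite(X)] <- Xt
  X[X > Xt] <- Xt
  X[friction$mask] <- Xt
  X[sources] <- 0
  structure(list(X = X, Xt = Xt, sources = sources), class = "lm_cost")
}

#' Theoretical maximum accumulated cost of a friction surface
#'
#' Grid diagonal length in cell steps times the maximum unmasked friction —
#' the worst-case straight traverse of the whole grid. Overridable wherever
#' it is consumed.
#'
#' @param friction an `lm_friction`.
#' @return positive scalar.
#' @export
theoretical_max_cost <- function(friction) {
  f <- friction$cost[!friction$mask]
  if (!length(f)) empty_result("all cells are masked")
  nr <- nrow(friction$cost); nc <- ncol(friction$cost)
  diag_steps <- sqrt((nr - 1)^2 + (nc - 1)^2)
  max(diag_steps, 1) * max(f)
}

#' Per-area connectivity transform
#'
#' `ECI_b = 10 - 9 * (ln(1 + X_i) / ln(1 + X_t))^3` (default reading of the
#' published expression, whose exponent typography is ambiguous; the
#' alternative `exponent = "denominator"` divides by `ln(1 + X_t)^3`
#' literally). Decreasing in `X_i`; equals 10 at `X_i = 0` and, under the
#' default reading, 1 at `X_i = X_t`.
#'
#' @param X_i accumulated cost(s), >= 0.
#' @param X_t theoretical maximum cost, > 0.
#' @param exponent `"ratio"` (cubed ratio, default) or `"denominator"`.
#' @param strict if TRUE, `X_i > X_t` is an error; otherwise clamped with a
#'   warning.
#' @return ECI_b value(s); in [1, 10] for `X_i` in `[0, X_t]` under the
#'   default reading.
#' @export
eci_b <- function(X_i, X_t, exponent = c("ratio", "denominator"),
                  strict = FALSE) {
  exponent <- match.arg(exponent)
  if (any(X_i < 0)) invalid_argument("X_i must be non-negative")
  if (length(X_t) != 1 || X_t <= 0) invalid_argument("X_t must be a positive scalar")
  if (any(X_i > X_t)) {
    if (strict) invalid_argument("X_i exceeds X_t")
    warning("X_i exceeds X_t; clamping to X_t")
    X_i <- pmin(X_i, X_t)
  }
  if (exponent == "ratio") {
    10 - 9 * (log1p(X_i) / log1p(X_t))^3
  } else {
    10 - 9 * log1p(X_i) / log1p(X_t)^3
  }
}

#' Average per-area connectivity fields into the total ECI
#'
#' `ECI = sum(ECI_b) / m` over the m functional areas considered, per cell.
#'
#' @param fields list of per-area ECI_b matrices, identical shape.
#' @return matrix of per-cell ECI.
#' @export
eci_total <- function(fields) {
  if (!length(fields)) invalid_argument("at least one ECI_b field required")
  dims <- lapply(fields, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    validation_error("ECI_b fields have mismatched shapes")
  Reduce(`+`, fields) / length(fields)
}

# connected-component patch filter for source cells (rook adjacency)
source_cells <- function(raster, legend, area, min_patch = 1) {
  codes <- legend$code[!is.na(legend$functional_area) &
                         legend$functional_area == area]
  hit <- which(matrix(raster$grid %in% codes, nrow(raster$grid)))
  if (min_patch <= 1 || !length(hit)) return(hit)
  nr <- nrow(raster$grid)
  inset <- logical(nr * ncol(raster$grid)); inset[hit] <- TRUE
  lab <- integer(length(inset)); nxt <- 0L
  for (s in hit) {
    if (lab[s]) next
    nxt <- nxt + 1L
    queue <- s; lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nr + 1L; cl <- (cur - 1L) %/% nr + 1L
      for (nb in c(if (r > 1) cur - 1L, if (r < nr) cur + 1L,
                   cur - nr, cur + nr)) {
        if (nb >= 1 && nb <= length(inset) && inset[nb] && !lab[nb]) {
          lab[nb] <- nxt; queue <- c(queue, nb)
        }
      }
    }
  }
  sizes <- tabulate(lab[hit])
  hit[sizes[lab[hit]] >= min_patch]
}

#' Full ECI computation: per cell and per hexagon
#'
#' For each target functional area: build the friction surface, accumulate
#' least-cost distance from that area's source patches, transform with
#' [eci_b()]; average the per-area fields into the cell ECI and take
#' per-hexagon means over valid cells. Areas with no source cells on the
#' raster are skipped (m shrinks accordingly, with a warning).
#'
#' @param raster,legend,affinity,barriers see [build_friction()].
#' @param grid an `lm_hexgrid` (optional; omit for cell output only).
#' @param targets functional areas to use as connectivity targets
#'   (default the seven canonical areas intersected with the affinity names).
#' @param connectivity 4 or 8.
#' @param base_cost base traversal cost.
#' @param exponent see [eci_b()].
#' @param min_patch minimum source patch size in cells.
#' @param Xt_override fixed X_t (scalar) applied to every area, or NULL.
#' @return list with `cell` (ECI matrix), `per_area` (list of ECI_b
#'   matrices), `Xt` (named vector), `m`, and if `grid` given `hex`
#'   (data.frame `hex_id, eci, eci_rescaled` with the min–max [0, 10]
#'   rescaling alongside the raw index).
#' @export
compute_eci <- function(raster, legend, affinity, barriers = NULL,
                        grid = NULL, targets = NULL, connectivity = 8,
                        base_cost = 1, exponent = "ratio", min_patch = 1,
                        Xt_override = NULL) {
  targets <- targets %||% intersect(functional_areas(), rownames(affinity))
  bfld <- barrier_field(raster, legend, barriers)
  per_area <- list(); Xts <- numeric(0)
  for (b in targets) {
    src <- source_cells(raster, legend, b, min_patch)
    if (!length(src)) {
      warning(sprintf("no source cells for functional area '%s'; skipped", b))
      next
    }
    fr <- build_friction(raster, legend, affinity, barriers, b,
                         base_cost = base_cost, .barrier_field = bfld)
    Xt <- Xt_override %||% theoretical_max_cost(fr)
    ac <- accumulate_cost(fr, src, connectivity = connectivity, Xt = Xt)
    per_area[[b]] <- eci_b(ac$X, ac$Xt, exponent = exponent)
    Xts[b] <- ac$Xt
  }
  if (!length(per_area)) empty_result("no functional area has source cells")
  cell <- eci_total(per_area)
  out <- list(cell = cell, per_area = per_area, Xt = Xts, m = length(per_area))
  if (!is.null(grid)) {
    hex <- zonal_mean(raster, grid, cell)
    rng <- range(hex$value, na.rm = TRUE)
    hex$eci_rescaled <- if (diff(rng) > 0)
      (hex$value - rng[1]) / diff(rng) * 10 else hex$value
    names(hex)[names(hex) == "value"] <- "eci"
    out$hex <- hex
  }
  out
}

# per-hexagon mean of a cell field over valid (non-nodata) cells
zonal_mean <- function(raster, grid, field) {
  cc <- cell_centers(raster)
  nr <- nrow(raster$grid)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = ncol(raster$grid))
  ext <- attr(grid, "extent")
  inside <- px >= ext[1] & px <= ext[2] & py >= ext[3] & py <= ext[4]
  valid <- inside & as.vector(raster$grid) != raster$nodata
  hex <- rep(NA_integer_, length(px))
  hex[valid] <- assign_to_hex(grid, px[valid], py[valid])
  v <- as.vector(field)
  means <- tapply(v[valid], factor(hex[valid], levels = seq_len(nrow(grid))),
                  mean, na.rm = TRUE)
  data.frame(hex_id = grid$hex_id, value = as.numeric(means))
}
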