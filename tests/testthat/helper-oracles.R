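# Independent oracles used across tests. These deliberately re-derive results
# by brute force (path enumeration, per-cell loops, closed forms) rather than
# calling the implementation under test.

# exhaustive least-cost search by depth-first path enumeration with
# cost-bound pruning; edge cost = mean of endpoint frictions x step length
enumerate_least_cost <- function(cost, mask, sources, connectivity = 8) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- matrix(Inf, nr, nc)
  dfs <- function(r, c, acc) {
    if (acc >= best[r, c]) return(invisible(NULL))
    best[r, c] <<- acc
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (connectivity == 4 && dr != 0 && dc != 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (mask[r2, c2]) next
      step <- if (dr != 0 && dc != 0) sqrt(2) else 1
      dfs(r2, c2, acc + (cost[r, c] + cost[r2, c2]) / 2 * step)
    }
  }
  for (s in sources) {
    r <- (s - 1) %% nr + 1; c <- (s - 1) %/% nr + 1
    if (!mask[r, c]) dfs(r, c, 0)
  }
  best
}

# ray-casting point-in-polygon (open ring)
point_in_poly <- function(px, py, xy) {
  n <- nrow(xy); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# per-hexagon class tally by an explicit per-cell loop over regenerated
# (unclipped) hexagon rings; ties/multiple hits resolve to the lowest hex_id
oracle_composition <- function(raster, grid) {
  s <- attr(grid, "side"); ori <- attr(grid, "orientation")
  ang <- if (ori == "flat_top") (0:5) * pi / 3 else (0:5) * pi / 3 + pi / 6
  rings <- lapply(seq_len(nrow(grid)), function(i)
    cbind(grid$cx[i] + s * cos(ang), grid$cy[i] + s * sin(ang)))
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  cs <- raster$cell_size
  cls <- sort(unique(as.vector(raster$grid)))
  cls <- cls[cls != raster$nodata]
  counts <- matrix(0L, nrow(grid), length(cls),
                   dimnames = list(grid$hex_id, cls))
  ext <- attr(grid, "extent")
  for (ci in seq_len(nc)) for (ri in seq_len(nr)) {
    code <- raster$grid[ri, ci]
    if (code == raster$nodata) next
    px <- raster$origin[1] + (ci - 0.5) * cs
    py <- raster$origin[2] - (ri - 0.5) * cs
    if (px < ext[1] || px > ext[2] || py < ext[3] || py > ext[4]) next
    for (h in seq_len(nrow(grid))) {
      if (abs(px - grid$cx[h]) > 2 * s || abs(py - grid$cy[h]) > 2 * s) next
      if (point_in_poly(px, py, rings[[h]])) {
        counts[h, as.character(code)] <- counts[h, as.character(code)] + 1L
        break
      }
    }
  }
  counts
}

# random compositional predictor matrix (rows sum to 1), Dirichlet(1)
random_composition <- function(n, k, colnames_prefix = "P") {
  m <- matrix(stats::rexp(n * k), n, k)
  m <- m / rowSums(m)
  colnames(m) <- paste0(colnames_prefix, seq_len(k))
  m
}

# small raster with the given codes drawn uniformly
random_raster <- function(nr, nc, codes, cell_size = 100, seed = 1) {
  set.seed(seed)
  lc_raster(matrix(sample(codes, nr * nc, replace = TRUE), nr, nc),
            cell_size, origin = c(0, nr * cell_size))
}

simple_legend <- function(codes,
                          habitat = paste0("hab", codes),
                          fa = rep("forest", length(codes)),
                          barrier = rep(FALSE, length(codes))) {
  legend_table(codes, paste0("class", codes),
               rep("forest_seminatural", length(codes)),
               habitat_category = habitat, functional_area = fa,
               barrier_flag = barrier,
               area_set = unique(fa[!is.na(fa)]))
}
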