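#' Reference legend for the study-region-like synthetic landscape
#'
#' The Corine-level-3-derived legend used throughout: 27 land-cover rows
#' spanning forest/seminatural, agricultural, water, built and other
#' typologies, with the roll-up groups of the printed area table, the
#' habitat categories feeding the Shannon metric (eight habitats plus one
#' "no habitat" category grouping urban, industrial and degraded covers),
#' the functional ecological areas feeding the connectivity model, and
#' barrier flags on built and degraded covers.
#'
#' @return an `lm_legend`.
#' @export
ucrv_legend <- function() {
  path <- system.file("extdata", "table1_land_cover.csv", package = "landmetab")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$habitat_category[df$habitat_category == ""] <- NA_character_
  df$functional_area[df$functional_area == ""] <- NA_character_
  legend_table(df$code, df$name, df$typology, df$reclass_group,
               df$habitat_category, df$functional_area,
               as.logical(df$barrier_flag))
}

#' Printed per-class areas of the study-region land-cover table
#'
#' @return named numeric vector of class areas in hectares (names = codes),
#'   as printed in the source area table.
#' @export
table1_areas <- function() {
  path <- system.file("extdata", "table1_land_cover.csv", package = "landmetab")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$area_ha, df$code)
}

#' Default synthetic-landscape scenario
#'
#' A 60 x 100-cell, 500 m-resolution neutral landscape emulating the
#' valley/slope/highland zonation of the study region: a
#' monoculture-dominated flat band (sugarcane, urban, pastures), a
#' mixed-mosaic mid-slope band, and a natural highland band (dense forest,
#' paramo, shrubland), with a river crossing all bands and a road crossing
#' the valley. Band 1 is the top of the grid (the valley).
#'
#' @param nrow,ncol grid shape in cells.
#' @param cell_size cell edge (m).
#' @param clustering patch-cohesion parameter in [0, 1] (0 = spatially
#'   random; higher values grow larger patches).
#' @param seed RNG seed stored in the scenario.
#' @return a `landscape_scenario` list.
#' @export
ucrv_scenario <- function(nrow = 60, ncol = 100, cell_size = 500,
                          clustering = 0.55, seed = 1) {
  structure(list(
    nrow = nrow, ncol = ncol, cell_size = cell_size,
    clustering = clustering, seed = seed,
    bands = list(
      valley = list(
        frac = 0.40,
        mix = c(`11` = 0.78, `19` = 0.05, `18` = 0.03, `24` = 0.05,
                `25` = 0.01, `26` = 0.02, `16` = 0.03, `21` = 0.01,
                `22` = 0.01, `27` = 0.01)),
      slope = list(
        frac = 0.35,
        mix = c(`12` = 0.13, `13` = 0.04, `14` = 0.10, `15` = 0.14,
                `16` = 0.07, `10` = 0.04, `17` = 0.05, `18` = 0.05,
                `19` = 0.07, `8` = 0.12, `7` = 0.03, `20` = 0.02,
                `9` = 0.09, `4` = 0.04, `22` = 0.01)),
      highland = list(
        frac = 0.25,
        mix = c(`6` = 0.55, `5` = 0.22, `4` = 0.12, `9` = 0.04,
                `8` = 0.03, `1` = 0.01, `2` = 0.01, `3` = 0.01,
                `19` = 0.01))
    ),
    barriers = list(
      list(class = 21L, direction = "vertical", pos = 0.30, width = 1L),
      list(class = 24L, direction = "horizontal", pos = 0.20, width = 1L)
    )
  ), class = "landscape_scenario")
}

# largest-remainder apportionment of n cells to target proportions
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Generate a synthetic categorical landscape
#'
#' Modified-random-clusters allocation: within each zonation band, patch
#' nuclei are seeded per class and grown cell by cell (class round-robin over
#' seeded frontiers) until realised class counts match the band's target
#' proportions exactly; linear barrier features are rasterised last. Output
#' is a pure function of the scenario (including its seed).
#'
#' @param scenario a `landscape_scenario` (see [ucrv_scenario()]).
#' @return an `lm_raster`; origin (0, nrow * cell_size), nodata -9999.
#' @export
generate_landscape <- function(scenario) {
  nr <- scenario$nrow; nc <- scenario$ncol
  for (b in scenario$bands)
    if (abs(sum(b$mix) - 1) > 1e-9)
      invalid_argument("band mix proportions must sum to 1")
  set.seed(scenario$seed)
  grid <- matrix(NA_integer_, nr, nc)

  fracs <- vapply(scenario$bands, function(b) b$frac, numeric(1))
  row_breaks <- c(0, cumsum(apportion(fracs / sum(fracs), nr)))
  cl <- scenario$clustering
  for (bi in seq_along(scenario$bands)) {
    rows <- (row_breaks[bi] + 1):row_breaks[bi + 1]
    band <- scenario$bands[[bi]]
    cells <- as.vector(outer(rows, (seq_len(nc) - 1) * nr, `+`))
    ncell <- length(cells)
    codes <- as.integer(names(band$mix))
    targets <- apportion(band$mix, ncell)
    if (any(band$mix > 0 & targets == 0))
      invalid_argument("band proportions infeasible for grid size")
    if (cl <= 0) {
      grid[cells] <- sample(rep.int(codes, targets))
      next
    }
    mean_patch <- 1 + cl * 20
    assigned <- integer(nr * nc)  # class code per claimed cell, band-local use
    counts <- stats::setNames(integer(length(codes)), codes)
    frontier <- vector("list", length(codes))
    in_band <- logical(nr * nc); in_band[cells] <- TRUE
    n_nuclei <- pmax(1L, as.integer(ceiling(targets / mean_patch)))
    nuclei <- sample(cells, min(sum(n_nuclei), ncell))
    k <- 0L
    for (ci in seq_along(codes)) {
      take <- nuclei[(k + 1):min(k + n_nuclei[ci], length(nuclei))]
      k <- k + n_nuclei[ci]
      frontier[[ci]] <- take[!is.na(take)]
    }
    neighbors <- function(cell) {
      r <- (cell - 1L) %% nr + 1L
      c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L, cell - nr, cell + nr)
    }
    total_assigned <- 0L
    while (total_assigned < ncell) {
      progressed <- FALSE
      for (ci in seq_along(codes)) {
        if (counts[ci] >= targets[ci]) next
        claimed <- FALSE
        while (!claimed) {
          if (!length(frontier[[ci]])) {
            empty <- cells[assigned[cells] == 0L]
            if (!length(empty)) break
            frontier[[ci]] <- if (length(empty) == 1) empty
                              else sample(empty, 1)
          }
          pick <- if (length(frontier[[ci]]) == 1) 1L
                  else sample.int(length(frontier[[ci]]), 1)
          cell <- frontier[[ci]][pick]
          frontier[[ci]] <- frontier[[ci]][-pick]
          if (in_band[cell] && assigned[cell] == 0L) {
            assigned[cell] <- codes[ci]
            counts[ci] <- counts[ci] + 1L
            total_assigned <- total_assigned + 1L
            nb <- neighbors(cell)
            nb <- nb[nb >= 1 & nb <= nr * nc]
            nb <- nb[in_band[nb] & assigned[nb] == 0L]
            frontier[[ci]] <- c(frontier[[ci]], nb)
            claimed <- TRUE; progressed <- TRUE
          }
        }
      }
      if (!progressed) break
    }
    grid[cells] <- assigned[cells]
  }

  for (bar in scenario$barriers) {
    w <- bar$width
    if (bar$direction == "vertical") {
      col0 <- max(1L, round(bar$pos * nc))
      grid[, col0:min(nc, col0 + w - 1L)] <- bar$class
    } else {
      row0 <- max(1L, round(bar$pos * nr))
      grid[row0:min(nr, row0 + w - 1L), ] <- bar$class
    }
  }
  lc_raster(grid, scenario$cell_size,
            origin = c(0, nr * scenario$cell_size))
}

#' Zonation band of each hexagon centre
#'
#' @param grid an `lm_hexgrid` built over the landscape extent.
#' @param scenario the `landscape_scenario` that generated the landscape.
#' @return character vector of band names per hexagon.
#' @export
hex_band <- function(grid, scenario) {
  fracs <- vapply(scenario$bands, function(b) b$frac, numeric(1))
  fracs <- fracs / sum(fracs)
  top <- scenario$nrow * scenario$cell_size
  # bands run top-down; convert centre y to depth fraction from the top
  depth <- (top - grid$cy) / top
  breaks <- c(0, cumsum(fracs))
  breaks[length(breaks)] <- 1 + 1e-9
  names(scenario$bands)[findInterval(pmin(pmax(depth, 0), 1), breaks,
                                     rightmost.closed = TRUE)]
}

#' Generate a synthetic per-class NPP table
#'
#' Typology-driven draws reproducing the expected ordering of human
#' appropriation: built and degraded covers retain almost no production
#' (HANPP% near 100); sugarcane out-produces the potential vegetation under
#' irrigation (negative land-use change) but is heavily harvested (HANPP%
#' above 60); annual crops and mosaics sit at intermediate levels; pastures
#' lower still; natural covers near zero. All draws satisfy the NPP table
#' invariants by construction.
#'
#' @param legend an `lm_legend` (typologies and functional areas drive the
#'   draws).
#' @param seed RNG seed.
#' @return an `lm_npp` with one row per legend class.
#' @export
generate_npp <- function(legend, seed = 1) {
  set.seed(seed)
  n <- nrow(legend)
  npp0 <- stats::runif(n, 10, 14)
  nppact <- npph <- numeric(n)
  for (i in seq_len(n)) {
    ty <- legend$typology[i]; fa <- legend$functional_area[i]
    if (ty == "built") {
      nppact[i] <- stats::runif(1, 0.1, 0.5); npph[i] <- 0
    } else if (ty == "other") {
      nppact[i] <- stats::runif(1, 0.5, 1.5); npph[i] <- 0
    } else if (ty == "water") {
      npp0[i] <- stats::runif(1, 1, 2); nppact[i] <- npp0[i]; npph[i] <- 0
    } else if (!is.na(fa) && fa == "sugarcane") {
      nppact[i] <- stats::runif(1, 1.2, 1.5) * npp0[i]
      npph[i] <- 0.75 * nppact[i]
    } else if (ty == "agricultural") {
      mosaic <- !is.na(fa) && fa == "agroforestry_mosaic"
      nppact[i] <- stats::runif(1, if (mosaic) 0.8 else 0.7,
                                if (mosaic) 0.95 else 0.9) * npp0[i]
      npph[i] <- stats::runif(1, if (mosaic) 0.2 else 0.3,
                              if (mosaic) 0.35 else 0.5) * nppact[i]
    } else {
      nppact[i] <- stats::runif(1, 0.97, 1) * npp0[i]; npph[i] <- 0
    }
  }
  npp_table(legend$code, npp0, nppact, npph)
}

#' Latent supply/demand archetypes per land-cover class
#'
#' Builds the latent Likert matrices a synthetic expert panel perturbs:
#' typology-level archetypes (natural covers supply regulating and cultural
#' services and demand little; mosaics supply broadly; sugarcane supplies
#' biomass energy but demands heavily; built covers only demand).
#'
#' @param legend an `lm_legend`.
#' @return list with `supply` and `demand` matrices (21 services x classes).
#' @export
latent_service_matrix <- function(legend) {
  svc <- service_catalog()
  n_s <- nrow(svc); n_c <- nrow(legend)
  S <- matrix(0, n_s, n_c, dimnames = list(svc$code, legend$code))
  D <- matrix(0, n_s, n_c, dimnames = list(svc$code, legend$code))
  arche <- function(ty, fa) {
    if (ty == "built") return(c(0.3, 0.3, 0.3, 5))
    if (ty == "water") return(c(3.5, 4, 3.5, 1))
    if (ty == "other") return(c(0.5, 0.5, 0.5, 1))
    if (!is.na(fa) && fa == "sugarcane") return(c(3, 0.5, 0.5, 4))
    if (!is.na(fa) && fa == "pastures") return(c(3, 2, 2, 2.5))
    if (ty == "agricultural") return(c(4, 3.4, 3.2, 2))
    c(2, 4.5, 4, 0.5)  # forest and seminatural
  }
  sec <- svc$section
  for (j in seq_len(n_c)) {
    a <- arche(legend$typology[j], legend$functional_area[j])
    S[sec == "provisioning", j] <- a[1]
    S[sec == "regulation_support", j] <- a[2]
    S[sec == "cultural", j] <- a[3]
    D[, j] <- a[4]
  }
  list(supply = S, demand = D)
}

#' Generate a synthetic expert panel
#'
#' Each expert's score is the rounded latent value perturbed by ±1 with
#' probability `noise_p` (half up, half down), clipped to the 0–5 Likert
#' scale; deterministic per seed.
#'
#' @param legend an `lm_legend`.
#' @param n_experts panel size (default 27).
#' @param noise_p total perturbation probability per score (default 0.2).
#' @param latent optional list `supply`/`demand` of latent matrices
#'   (defaults to [latent_service_matrix()]).
#' @param seed RNG seed.
#' @return an `lm_panel`.
#' @export
generate_expert_panel <- function(legend, n_experts = 27, noise_p = 0.2,
                                  latent = NULL, seed = 1) {
  set.seed(seed)
  latent <- latent %||% latent_service_matrix(legend)
  if (any(latent$supply < 0 | latent$supply > 5) ||
      any(latent$demand < 0 | latent$demand > 5))
    invalid_argument("latent matrices must lie in [0, 5]")
  svc <- service_catalog()
  n_s <- nrow(svc); n_c <- ncol(latent$supply)
  base_s <- round(latent$supply); base_d <- round(latent$demand)
  perturb <- function(base) {
    u <- stats::runif(length(base))
    delta <- ifelse(u < noise_p / 2, -1L, ifelse(u < noise_p, 1L, 0L))
    pmin(pmax(as.integer(base) + delta, 0L), 5L)
  }
  out <- vector("list", n_experts)
  covers <- as.integer(colnames(latent$supply))
  for (e in seq_len(n_experts)) {
    out[[e]] <- data.frame(
      expert_id = sprintf("E%02d", e),
      service_code = rep(svc$code, times = n_c),
      section = rep(svc$section, times = n_c),
      cover = rep(covers, each = n_s),
      supply = perturb(base_s),
      demand = perturb(base_d),
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, out)
  expert_responses(all$expert_id, all$service_code, all$section, all$cover,
                   all$supply, all$demand)
}
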