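test_that("hexagon design yields the expected analysis-unit counts", {
  # 1,004,000 ha at 2,000 ha per unit -> 502 units, from real clipped geometry
  hg <- build_hex_grid(c(0, 100400, 0, 100000), 2000)
  expect_equal(attr(hg, "units_equivalent"), 502L)
  expect_equal(sum(hg$area_ha), 1004000, tolerance = 1e-9)
  expect_equal(n_analysis_units(1004000, 2000), 502L)

  # extent of exactly one cell's area -> a single analysis unit
  side <- sqrt(2000 * 1e4)
  one <- build_hex_grid(c(0, side, 0, side), 2000)
  expect_equal(attr(one, "units_equivalent"), 1L)
  expect_equal(sum(one$area_ha), 2000, tolerance = 1e-9)

  # interior hexagons all have the nominal area
  interior <- hg$area_ha[!hg$clipped]
  expect_true(length(interior) > 100)
  expect_equal(interior, rep(2000, length(interior)), tolerance = 1e-6)
})

test_that("clipped hexagon areas sum to the extent area (shoelace oracle)", {
  # 10 km x 10 km extent, 100 ha cells: clipped area must total 10,000 ha
  hg <- build_hex_grid(c(0, 10000, 0, 10000), 100)
  rings <- attr(hg, "vertices")
  shoelace <- function(xy) {
    x <- xy[, 1]; y <- xy[, 2]; n <- nrow(xy); j <- c(n, seq_len(n - 1))
    abs(sum(x[j] * y - x * y[j])) / 2
  }
  oracle_total <- sum(vapply(rings, shoelace, numeric(1))) / 1e4
  expect_equal(sum(hg$area_ha), oracle_total, tolerance = 1e-9)
  expect_equal(oracle_total, 10000, tolerance = 1e-6)
  expect_equal(attr(hg, "units_equivalent"), 100L)
})

test_that("hex grid generation is deterministic and validates arguments", {
  a <- build_hex_grid(c(0, 5000, 0, 5000), 50)
  b <- build_hex_grid(c(0, 5000, 0, 5000), 50)
  expect_identical(a$cx, b$cx)
  expect_identical(attr(a, "vertices"), attr(b, "vertices"))
  expect_error(build_hex_grid(c(0, 0, 0, 100), 10), class = "landmetab_invalid_argument")
  expect_error(build_hex_grid(c(0, 100, 0, 100), -5), class = "landmetab_invalid_argument")
})

test_that("composition matches the brute-force per-cell tally", {
  set.seed(42)
  r <- lc_raster(matrix(sample(1:5, 3600, replace = TRUE), 60, 60),
                 100, origin = c(0, 6000))
  hg <- build_hex_grid(c(0, 6000, 0, 6000), 120)
  comp <- compute_composition(r, hg, min_valid_fraction = 0.5)
  oracle <- oracle_composition(r, hg)
  oracle_P <- oracle / ifelse(rowSums(oracle) > 0, rowSums(oracle), NA)
  keep <- !comp$excluded
  expect_equal(comp$P[keep, ], oracle_P[keep, ], tolerance = 1e-12)
  # conservation on retained hexagons
  expect_equal(unname(rowSums(comp$P[keep, , drop = FALSE])),
               rep(1, sum(keep)), tolerance = 1e-9)
})

test_that("composition handles uniform and split-class rasters", {
  r <- lc_raster(matrix(7L, 30, 30), 100, origin = c(0, 3000))
  hg <- build_hex_grid(c(0, 3000, 0, 3000), 50)
  comp <- compute_composition(r, hg)
  keep <- !comp$excluded
  expect_true(all(comp$P[keep, "7"] == 1))

  g <- matrix(1L, 30, 30); g[, 16:30] <- 2L
  comp2 <- compute_composition(lc_raster(g, 100, origin = c(0, 3000)), hg)
  keep2 <- !comp2$excluded
  expect_equal(unname(rowSums(comp2$P[keep2, ])), rep(1, sum(keep2)))

  far <- lc_raster(matrix(1L, 5, 5), 100, origin = c(1e6, 1e6))
  expect_error(compute_composition(far, hg), class = "landmetab_empty_result")
})

test_that("area summaries reproduce printed class and group arithmetic", {
  lg <- ucrv_legend()
  at <- area_table(table1_areas(), lg, percent_base = 1004000)
  g <- area_groups(at)
  gv <- function(nm) g$area_ha[g$reclass == nm]
  expect_equal(gv("Total others"), 611.44, tolerance = 1e-9)
  expect_equal(gv("Total urban and industrial areas"), 23954.63, tolerance = 1e-9)
  expect_equal(round_half_up(gv("Total primary forest"), 1), 120174.7)
  expect_equal(round_half_up(gv("Total permanent crops"), 1), 196377.5)
  expect_equal(round_half_up(at$percent[at$code == 11], 1), 19.2)
  expect_equal(round_half_up(g$percent[g$reclass == "Total agricultural mosaics"], 1), 31.1)
  # group sums are exact sums of members; grand total is the class sum
  for (k in seq_len(nrow(g))) {
    expect_equal(g$area_ha[k], sum(at$area_ha[at$reclass == g$reclass[k]]))
  }
  expect_equal(attr(at, "total_ha"), sum(at$area_ha))
})

test_that("summarize_areas counts cells and respects nodata", {
  lg <- simple_legend(1:2)
  g <- matrix(1L, 10, 10); g[1:2, ] <- -9999L
  r <- lc_raster(g, 100, origin = c(0, 1000))
  at <- summarize_areas(r, lg)
  expect_equal(at$area_ha[at$code == 1], 80 * 1)  # 80 valid cells x 1 ha
  expect_equal(at$percent[at$code == 1], 100)
  allnd <- lc_raster(matrix(-9999L, 3, 3), 100)
  expect_error(summarize_areas(allnd, lg), class = "landmetab_empty_result")
})

test_that("reclassification conserves area and validates coverage", {
  set.seed(9)
  r <- random_raster(20, 20, 1:3, seed = 9)
  idmap <- stats::setNames(1:3, 1:3)
  expect_identical(reclassify(r, idmap)$grid, r$grid)

  m <- stats::setNames(c(10L, 10L, 20L), 1:3)
  r2 <- reclassify(r, m)
  n1 <- sum(r$grid == 1); n2 <- sum(r$grid == 2)
  expect_equal(sum(r2$grid == 10), n1 + n2)  # direct cell-count oracle
  expect_equal(sum(r2$grid != r2$nodata), sum(r$grid != r$nodata))
  expect_error(reclassify(r, m[1:2]), class = "landmetab_validation_error")
})
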