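make_friction <- function(cost, cell_size = 100) {
  structure(list(cost = cost, mask = is.na(cost), cell_size = cell_size),
            class = "lm_friction")
}

test_that("friction combines affinity division and barrier halos", {
  aff <- affinity_matrix(matrix(c(1, 0.5, 0.5, 1), 2, 2,
                                dimnames = list(c("forest", "crops"),
                                                c("forest", "crops"))))
  lg <- legend_table(1:2, c("f", "c"), "forest_seminatural",
                     functional_area = c("forest", "crops"),
                     area_set = c("forest", "crops"))
  r <- lc_raster(matrix(c(1L, 2L), 1, 2), 100)
  fr <- build_friction(r, lg, aff, target_area = "forest")
  expect_equal(fr$cost[1, 1], 1)       # same area, affinity 1 -> base cost
  expect_equal(fr$cost[1, 2], 1 / 0.5) # affinity 0.5 doubles friction

  # halo oracle: one barrier cell, impact 5, radius 2 cells on a 10x10 grid
  lgb <- legend_table(1:2, c("f", "road"), c("forest_seminatural", "built"),
                      functional_area = c("forest", NA),
                      barrier_flag = c(FALSE, TRUE),
                      area_set = "forest")
  g <- matrix(1L, 10, 10); g[5, 5] <- 2L
  rb <- lc_raster(g, 100, origin = c(0, 1000))
  bar <- barrier_spec(2L, impact = 5, halo_m = 200)
  frb <- build_friction(rb, lgb, affinity_matrix(matrix(1, 1, 1,
    dimnames = list("forest", "forest"))), bar, "forest")
  oracle <- matrix(1, 10, 10)
  for (ri in 1:10) for (ci in 1:10) {
    if ((ri - 5)^2 + (ci - 5)^2 <= 4 + 1e-9) oracle[ri, ci] <- oracle[ri, ci] + 5
  }
  oracle[5, 5] <- 1 / 1 + 5  # barrier cell itself travels at worst affinity = 1 here
  expect_equal(frb$cost, oracle)

  # class with neither functional area nor barrier flag -> validation error
  lg_bad <- legend_table(1:2, c("f", "x"), "forest_seminatural",
                         functional_area = c("forest", NA),
                         area_set = "forest")
  expect_error(build_friction(rb, lg_bad, affinity_matrix(matrix(1, 1, 1,
    dimnames = list("forest", "forest"))), NULL, "forest"),
    class = "landmetab_validation_error")
})

test_that("accumulated cost is exact on uniform grids and at sources", {
  f <- make_friction(matrix(2, 5, 5))
  ac <- accumulate_cost(f, sources = 1L, connectivity = 4, Xt = 1e9)
  # uniform friction, 4-connectivity: cost = friction x Manhattan distance
  for (ci in 1:5) for (ri in 1:5) {
    expect_equal(ac$X[ri, ci], 2 * ((ri - 1) + (ci - 1)))
  }
  expect_equal(ac$X[1, 1], 0)
  expect_error(accumulate_cost(f, integer(0)), class = "landmetab_invalid_argument")
  fm <- make_friction(matrix(c(NA, 1, 1, 1), 2, 2))
  expect_error(accumulate_cost(fm, sources = 1L), class = "landmetab_empty_result")
})

test_that("Dijkstra equals exhaustive path enumeration on small random grids", {
  for (seed in 1:6) {
    set.seed(seed)
    for (conn in c(4, 8)) {
      cost <- matrix(stats::runif(16, 0.2, 3), 4, 4)
      src <- sample(1:16, 2)
      f <- make_friction(cost)
      ac <- accumulate_cost(f, src, connectivity = conn, Xt = 1e9)
      oracle <- enumerate_least_cost(cost, matrix(FALSE, 4, 4), src, conn)
      expect_equal(ac$X, oracle, tolerance = 1e-10)
    }
  }
})

test_that("theoretical maximum cost scales with friction and grid diagonal", {
  f <- make_friction(matrix(1, 10, 10))
  expect_equal(theoretical_max_cost(f), sqrt(81 + 81))
  f2 <- make_friction(matrix(2, 10, 10))
  expect_equal(theoretical_max_cost(f2), 2 * theoretical_max_cost(f))
  set.seed(3)
  fr <- matrix(stats::runif(30, 0.1, 7), 5, 6)
  expect_equal(theoretical_max_cost(make_friction(fr)),
               sqrt(16 + 25) * max(fr))
})

test_that("the connectivity transform hits its endpoints and decreases", {
  expect_equal(eci_b(0, 100), 10)
  expect_equal(eci_b(100, 100), 1)
  # direct arithmetic evaluation of the printed expression
  expect_equal(eci_b(10, 100), 10 - 9 * (log(11) / log(101))^3)
  xs <- seq(0, 50, length.out = 101)
  expect_true(all(diff(eci_b(xs, 50)) < 0))
  expect_true(all(eci_b(xs, 50) >= 1 & eci_b(xs, 50) <= 10))
  expect_warning(v <- eci_b(150, 100), "clamping")
  expect_equal(v, 1)
  expect_error(eci_b(150, 100, strict = TRUE), class = "landmetab_invalid_argument")
  # alternative exponent reading is still 10 at zero cost
  expect_equal(eci_b(0, 100, exponent = "denominator"), 10)
})

test_that("per-area fields average into the total ECI", {
  a <- matrix(10, 3, 3); b <- matrix(1, 3, 3)
  expect_equal(eci_total(list(a, a)), a)
  expect_equal(eci_total(list(a, b)), matrix(5.5, 3, 3))
  set.seed(3)
  fs <- replicate(3, matrix(stats::runif(9, 1, 10), 3, 3), simplify = FALSE)
  expect_equal(eci_total(fs), (fs[[1]] + fs[[2]] + fs[[3]]) / 3)
  expect_error(eci_total(list(a, matrix(1, 2, 2))),
               class = "landmetab_validation_error")
})

test_that("barriers and lower affinity never increase connectivity", {
  lg <- legend_table(1:3, c("forest", "crops", "road"),
                     c("forest_seminatural", "agricultural", "built"),
                     functional_area = c("forest", "crops", NA),
                     barrier_flag = c(FALSE, FALSE, TRUE),
                     area_set = c("forest", "crops"))
  set.seed(11)
  g <- matrix(sample(1:2, 100, replace = TRUE, prob = c(0.3, 0.7)), 10, 10)
  g[1, 1] <- 1L
  base_aff <- affinity_matrix(matrix(c(1, 0.6, 0.6, 1), 2, 2,
    dimnames = list(c("forest", "crops"), c("forest", "crops"))))
  low_aff <- affinity_matrix(matrix(c(1, 0.2, 0.2, 1), 2, 2,
    dimnames = list(c("forest", "crops"), c("forest", "crops"))))
  r <- lc_raster(g, 100, origin = c(0, 1000))
  Xt <- 500
  eci_of <- function(aff, bars, rr) {
    res <- compute_eci(rr, lg, aff, bars, targets = "forest", Xt_override = Xt)
    res$per_area$forest
  }
  e_base <- eci_of(base_aff, NULL, r)
  e_low <- eci_of(low_aff, NULL, r)
  expect_true(all(e_low <= e_base + 1e-12))
  g2 <- g; g2[5, ] <- ifelse(g2[5, ] == 1L, g2[5, ], 3L)
  r2 <- lc_raster(g2, 100, origin = c(0, 1000))
  e_bar <- eci_of(base_aff, barrier_spec(3L, impact = 8, halo_m = 150), r2)
  cells_same <- g2 == g  # forest sources unchanged there
  expect_true(all(e_bar[cells_same] <= e_base[cells_same] + 1e-12))
})

test_that("ECI on a uniform landscape is invariant to joint cost scaling", {
  # every cell is a source, so accumulated costs are zero and ECI is 10
  # regardless of multiplying friction and X_t by the same constant
  lg <- simple_legend(1L, fa = "forest")
  r <- lc_raster(matrix(1L, 8, 8), 100, origin = c(0, 800))
  aff <- affinity_matrix(matrix(1, 1, 1, dimnames = list("forest", "forest")))
  a1 <- compute_eci(r, lg, aff, targets = "forest", base_cost = 1)
  a2 <- compute_eci(r, lg, aff, targets = "forest", base_cost = 5)
  expect_equal(a1$cell, matrix(10, 8, 8))
  expect_identical(a1$cell, a2$cell)
})
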