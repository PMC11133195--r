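tiny_panel <- function(scores_s, scores_d, covers = 1L) {
  n_e <- length(scores_s)
  svc <- service_catalog()
  rows <- expand.grid(e = seq_len(n_e), s = seq_len(nrow(svc)),
                      cov = covers)
  expert_responses(paste0("E", rows$e), svc$code[rows$s],
                   svc$section[rows$s], rows$cov,
                   supply = scores_s[rows$e], demand = scores_d[rows$e])
}

test_that("panel aggregation averages expert scores per cell", {
  p <- tiny_panel(c(3L, 3L, 3L), c(1L, 1L, 1L))
  m <- aggregate_panel(p)
  expect_true(all(m$supply == 3))
  expect_true(all(m$demand == 1))
  expect_true(all(m$count == 3))

  p2 <- tiny_panel(c(0L, 5L), c(2L, 4L))
  m2 <- aggregate_panel(p2)
  expect_true(all(m2$supply == 2.5))
  expect_true(all(m2$demand == 3))

  # 27 simulated experts vs explicit sum/count oracle
  lg <- ucrv_legend()
  panel <- generate_expert_panel(lg, n_experts = 27, seed = 5)
  m3 <- aggregate_panel(panel)
  cell <- panel[panel$service_code == "2.3.5" & panel$cover == 6, ]
  expect_equal(m3$supply["2.3.5", "6"], sum(cell$supply) / nrow(cell))
  expect_equal(unname(m3$count["2.3.5", "6"]), 27)
})

test_that("panel invariants: identical experts and mean-expert no-ops", {
  p1 <- tiny_panel(c(4L, 4L, 4L, 4L), c(1L, 1L, 1L, 1L))
  single <- tiny_panel(4L, 1L)
  expect_equal(aggregate_panel(p1)$supply, aggregate_panel(single)$supply)
  # adding an expert scoring the current mean leaves the matrix unchanged
  p2 <- tiny_panel(c(2L, 4L), c(0L, 2L))
  p3 <- tiny_panel(c(2L, 4L, 3L), c(0L, 2L, 1L))
  expect_equal(aggregate_panel(p3)$supply, aggregate_panel(p2)$supply)
  expect_equal(aggregate_panel(p3)$demand, aggregate_panel(p2)$demand)
})

test_that("capacity is supply minus demand on the Likert scale", {
  expect_equal(capacity(0, 5), -5)
  expect_equal(capacity(3.2, 3.2), 0)
  expect_equal(capacity(4.2, 1.1), 3.1)
  expect_error(capacity(6, 0), class = "landmetab_invalid_argument")
})

test_that("per-cover capacity averages service capacities", {
  p <- tiny_panel(3L, 3L)
  expect_equal(unname(cover_capacity(aggregate_panel(p))), 0)
  # half the services at +5, half at -5 -> 0 (constructed matrix)
  m <- aggregate_panel(tiny_panel(5L, 0L))
  half <- seq_len(nrow(m$supply)) <= nrow(m$supply) / 2
  m$supply[half, ] <- 0; m$demand[half, ] <- 5
  # 21 services: 10 at -5, 11 at +5 is not symmetric, so force an even split
  m$supply[11, ] <- 2.5; m$demand[11, ] <- 2.5
  expect_equal(unname(cover_capacity(m)), (10 * -5 + 10 * 5 + 0) / 21)

  set.seed(9)
  sup <- matrix(stats::runif(42, 0, 5), 21, 2,
                dimnames = list(service_catalog()$code, 1:2))
  dem <- matrix(stats::runif(42, 0, 5), 21, 2, dimnames = dimnames(sup))
  m2 <- list(supply = sup, demand = dem, count = sup * 0 + 1,
             section = stats::setNames(service_catalog()$section,
                                       service_catalog()$code))
  expect_equal(unname(cover_capacity(m2)), unname(colMeans(sup - dem)))
})

test_that("multifunctionality counts provided services per section", {
  m_all <- aggregate_panel(tiny_panel(5L, 0L))
  expect_equal(unname(cover_multifunctionality(m_all)), 5)
  m_none <- aggregate_panel(tiny_panel(1L, 0L))
  expect_equal(unname(cover_multifunctionality(m_none)), 0)
  # one full section, two empty -> 5/3
  m <- m_all
  sec <- m$section[rownames(m$supply)]
  m$supply[sec != "provisioning", ] <- 0
  expect_equal(unname(cover_multifunctionality(m)), 5 / 3)
})

test_that("hexagon service scores are composition-weighted", {
  P <- matrix(c(1, 0.5, 0, 0.5), 2, 2, dimnames = list(1:2, c("1", "2")))
  comp <- structure(list(P = P, excluded = c(FALSE, FALSE),
                         valid_fraction = c(1, 1), n_valid = c(10L, 10L),
                         cell_area_ha = 1, hex_id = 1:2),
                    class = "lm_composition")
  esc_i <- c(`1` = -2, `2` = 4); mf_i <- c(`1` = 1, `2` = 3)
  hx <- esc_hex(comp, esc_i, mf_i)
  expect_equal(hx$esc, c(-2, 1))
  expect_equal(hx$mf, c(1, 2))
  expect_error(esc_hex(comp, esc_i[1], mf_i),
               class = "landmetab_validation_error")

  set.seed(13)
  P2 <- matrix(stats::rexp(12), 3, 4); P2 <- P2 / rowSums(P2)
  dimnames(P2) <- list(1:3, 1:4)
  comp2 <- structure(list(P = P2, excluded = rep(FALSE, 3),
                          valid_fraction = rep(1, 3), n_valid = rep(10L, 3),
                          cell_area_ha = 1, hex_id = 1:3),
                     class = "lm_composition")
  e2 <- stats::setNames(stats::runif(4, -5, 5), 1:4)
  m2 <- stats::setNames(stats::runif(4, 0, 5), 1:4)
  hx2 <- esc_hex(comp2, e2, m2)
  oracle <- sapply(1:3, function(i) sum(P2[i, ] * e2))
  expect_equal(hx2$esc, oracle)
  # convex-combination bounds
  expect_true(all(hx2$esc >= min(e2) - 1e-12 & hx2$esc <= max(e2) + 1e-12))
  expect_true(all(hx2$mf >= min(m2) - 1e-12 & hx2$mf <= max(m2) + 1e-12))
})
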