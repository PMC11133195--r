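test_that("OLS matches the closed-form normal-equation oracle", {
  set.seed(2)
  X <- random_composition(40, 4)
  y <- 0.3 + X %*% c(1, -2, 0.5, 0) + stats::rnorm(40, sd = 0.1)
  fit <- stepwise_mrm(y, X, criterion = "AIC")
  # refit the selected model by solving the normal equations directly
  Xs <- cbind(1, X[, fit$selected, drop = FALSE])
  beta <- solve(t(Xs) %*% Xs, t(Xs) %*% y)
  expect_equal(unname(fit$coefficients$estimate), unname(as.numeric(beta)),
               tolerance = 1e-10)

  lf <- linear_fit(X[, 1], y)
  xc <- X[, 1]
  b1 <- sum((xc - mean(xc)) * (y - mean(y))) / sum((xc - mean(xc))^2)
  expect_equal(lf$slope, b1, tolerance = 1e-10)
  expect_equal(lf$intercept, mean(y) - b1 * mean(xc), tolerance = 1e-10)
})

test_that("noiseless responses are recovered exactly", {
  set.seed(4)
  X <- random_composition(120, 10)
  y <- 0.45 - 0.3 * X[, 2] + 0.25 * X[, 7]
  fit <- suppressWarnings(stepwise_mrm(y, X))  # perfect fit warns in summary.lm
  expect_setequal(fit$selected, c("P2", "P7"))
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["Intercept"]), 0.45, tolerance = 1e-8)
  expect_equal(unname(est["P2"]), -0.3, tolerance = 1e-8)
  expect_equal(unname(est["P7"]), 0.25, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("stepwise selection is deterministic for fixed data", {
  set.seed(6)
  X <- random_composition(100, 8)
  y <- 0.4 + X %*% c(0.5, 0, -0.4, 0, 0, 0.2, 0, 0) + stats::rnorm(100, sd = 0.05)
  f1 <- stepwise_mrm(y, X)
  f2 <- stepwise_mrm(y, X)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(format_regression(f1), format_regression(f2))
})

test_that("constant predictors are dropped and reported", {
  set.seed(8)
  X <- cbind(random_composition(60, 3), Z = 0)
  y <- 0.2 + X[, 1] + stats::rnorm(60, sd = 0.05)
  fit <- stepwise_mrm(y, X)
  expect_equal(fit$dropped_constant, "Z")
  expect_false("Z" %in% fit$selected)
})

test_that("noisy coefficient recovery hits the 95% intervals across seeds", {
  n_rep <- 100
  selected_both <- 0L
  coverage <- c(P3 = 0L, P11 = 0L)
  truth <- c(P3 = -0.6, P11 = 0.5)
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    X <- random_composition(502, 22)
    y <- 0.45 + truth["P3"] * X[, 3] + truth["P11"] * X[, 11] +
      stats::rnorm(502, sd = 0.05)
    fit <- stepwise_mrm(y, X)
    if (all(names(truth) %in% fit$selected)) selected_both <- selected_both + 1L
    co <- fit$coefficients
    for (term in names(truth)) {
      row <- co[co$term == term, ]
      if (nrow(row) != 1) next
      ci <- row$estimate +
        c(-1, 1) * stats::qt(0.975, fit$df_residual) * row$std_error
      if (truth[term] >= ci[1] && truth[term] <= ci[2])
        coverage[term] <- coverage[term] + 1L
    }
  }
  expect_equal(selected_both, n_rep)  # true covers always selected
  expect_gte(min(coverage), 90L)     # each 95% CI covers in >= 90/100 seeds
})

test_that("pure-noise responses keep per-predictor false positives rare", {
  set.seed(17)
  n_rep <- 100
  sig_count <- stats::setNames(integer(22), paste0("P", 1:22))
  for (rep in seq_len(n_rep)) {
    X <- random_composition(200, 22)
    y <- stats::rnorm(200)
    fit <- stepwise_mrm(y, X)
    co <- fit$coefficients
    hits <- co$term[co$significant & co$term != "Intercept"]
    sig_count[hits] <- sig_count[hits] + 1L
  }
  # no single cover is flagged significant in anything close to 90% of runs
  expect_true(all(sig_count < 0.5 * n_rep))
  # and the per-predictor false-positive rate stays near the nominal level
  expect_lt(mean(sig_count) / n_rep, 0.10)
})

test_that("the linear fit matches its examples and degenerate rules", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  lf <- suppressWarnings(linear_fit(x, 2 * x + 1))
  expect_equal(lf$slope, 2, tolerance = 1e-12)
  expect_equal(lf$intercept, 1, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1, tolerance = 1e-12)

  set.seed(23)
  r2 <- replicate(20, {
    xx <- stats::runif(500); yy <- stats::rnorm(500)
    linear_fit(xx, yy)$r_squared
  })
  expect_true(mean(r2 < 0.05) > 0.9)
  expect_error(linear_fit(rep(1, 5), 1:5), class = "landmetab_invalid_argument")
  expect_error(linear_fit(1:2, 1:2), class = "landmetab_invalid_argument")
})

test_that("the regression report carries the full statistics block", {
  set.seed(31)
  X <- random_composition(150, 6)
  y <- 0.4 + 0.8 * X[, 1] - 0.5 * X[, 4] + stats::rnorm(150, sd = 0.05)
  fit <- stepwise_mrm(y, X)
  expect_true(fit$adj_r_squared <= fit$r_squared)
  expect_identical(unname(fit$coefficients$significant),
                   unname(fit$coefficients$p_value < 0.05))
  rq <- fit$residual_quantiles
  expect_true(all(diff(rq) >= 0))
  expect_equal(fit$n, 150)
  txt <- format_regression(fit)
  expect_true(any(grepl("Residuals:", txt)))
  expect_true(any(grepl("R-squared", txt)))
  expect_true(any(grepl("F-statistic", txt)))
  expect_true(any(grepl("Significance codes", txt)))
})
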