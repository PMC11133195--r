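# AIC on the Gaussian profile likelihood scale: n log(RSS/n) + 2k
.aic_rss <- function(rss, n, k) n * log(rss / n) + 2 * k

.fit_rss <- function(y, Xmat) {
  f <- stats::lm.fit(cbind(`(Intercept)` = 1, Xmat), y)
  sum(f$residuals^2)
}

#' Stepwise multiple regression of a response on cover-class proportions
#'
#' Bidirectional stepwise selection over the predictor columns with ordinary
#' least squares at every step. The default criterion is AIC (add or drop
#' whichever single term lowers AIC most, stop when no move improves);
#' `criterion = "pvalue"` uses classic enter/remove thresholds instead.
#' Selection is fully deterministic: candidates are scanned in fixed column
#' order and there is no randomness. Constant (zero-variance) predictors are
#' dropped before selection and listed in the result; a perfect fit
#' (residual sum of squares at numerical zero) stops selection immediately.
#'
#' @param response numeric response per observation (e.g. per-hexagon IDC).
#' @param predictors numeric matrix or data.frame of candidate predictors
#'   (e.g. the cover-proportion columns of an `lm_composition`).
#' @param criterion `"AIC"` (default) or `"pvalue"`.
#' @param enter,remove p-value thresholds for `criterion = "pvalue"`
#'   (defaults 0.05 / 0.10).
#' @param alpha significance-flag level for the report (default 0.05).
#' @return an `lm_mrm`: list with `coefficients` (term, estimate, std_error,
#'   t_value, p_value, significant), `r_squared`, `adj_r_squared`, `sigma`,
#'   `fstatistic` (`value, df1, df2`), `residual_quantiles`, `n`, `selected`,
#'   `dropped_constant`, `aliased`, `criterion`.
#' @export
stepwise_mrm <- function(response, predictors,
                         criterion = c("AIC", "pvalue"),
                         enter = 0.05, remove = 0.10, alpha = 0.05) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(predictors)
  y <- as.numeric(response)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < ncol(X) + 2 && criterion == "AIC" && n < 3)
    invalid_argument("too few observations")
  const <- vapply(X, function(v) stats::var(v) == 0, logical(1))
  dropped_constant <- names(X)[const]
  X <- X[, !const, drop = FALSE]
  cand <- names(X)
  Xm <- as.matrix(X)
  rss_tol <- max(1e-20, 1e-14 * sum((y - mean(y))^2))

  sel <- character(0)
  if (criterion == "AIC") {
    cur_rss <- sum((y - mean(y))^2)
    cur_aic <- .aic_rss(cur_rss, n, 1)
    repeat {
      if (cur_rss <= rss_tol) break
      best <- list(aic = cur_aic, move = NULL)
      for (v in setdiff(cand, sel)) {
        rss <- .fit_rss(y, Xm[, c(sel, v), drop = FALSE])
        a <- .aic_rss(max(rss, rss_tol / 10), n, length(sel) + 2)
        if (a < best$aic - 1e-8) best <- list(aic = a, move = c("add", v), rss = rss)
      }
      for (v in sel) {
        rss <- .fit_rss(y, Xm[, setdiff(sel, v), drop = FALSE])
        a <- .aic_rss(max(rss, rss_tol / 10), n, length(sel))
        if (a < best$aic - 1e-8) best <- list(aic = a, move = c("drop", v), rss = rss)
      }
      if (is.null(best$move)) break
      sel <- if (best$move[1] == "add") c(sel, best$move[2])
             else setdiff(sel, best$move[2])
      cur_aic <- best$aic; cur_rss <- best$rss
    }
  } else {
    repeat {
      changed <- FALSE
      pool <- setdiff(cand, sel)
      if (length(pool)) {
        ps <- vapply(pool, function(v) {
          fit <- stats::lm(y ~ ., data = data.frame(X[, c(sel, v), drop = FALSE]))
          cf <- summary(fit)$coefficients
          cf[nrow(cf), 4]
        }, numeric(1))
        if (min(ps) < enter) {
          sel <- c(sel, pool[which.min(ps)]); changed <- TRUE
        }
      }
      if (length(sel)) {
        fit <- stats::lm(y ~ ., data = data.frame(X[, sel, drop = FALSE]))
        cf <- summary(fit)$coefficients
        ps <- cf[-1, 4]
        if (length(ps) && max(ps) > remove) {
          sel <- setdiff(sel, sel[which.max(ps)]); changed <- TRUE
        }
      }
      rss <- if (length(sel)) .fit_rss(y, Xm[, sel, drop = FALSE])
             else sum((y - mean(y))^2)
      if (!changed || rss <= rss_tol) break
    }
  }

  dat <- data.frame(.y = y, X[, sel, drop = FALSE], check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  co <- data.frame(
    term = rownames(cf),
    estimate = cf[, 1], std_error = cf[, 2],
    t_value = cf[, 3], p_value = cf[, 4],
    significant = cf[, 4] < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  co$term[co$term == "(Intercept)"] <- "Intercept"
  co$term <- gsub("^`|`$", "", co$term)
  rq <- stats::quantile(stats::residuals(fit), c(0, 0.25, 0.5, 0.75, 1))
  names(rq) <- c("min", "q1", "median", "q3", "max")
  fs <- sm$fstatistic
  structure(list(
    coefficients = co,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    df_residual = fit$df.residual,
    fstatistic = if (!is.null(fs))
      list(value = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]))
      else NULL,
    residual_quantiles = rq,
    n = n, selected = sel,
    dropped_constant = dropped_constant,
    aliased = aliased,
    criterion = criterion, alpha = alpha
  ), class = "lm_mrm")
}

#' Format a stepwise regression result as a plain-text report
#'
#' Residual quantiles, the coefficient block with a significance column, and
#' the fit-statistics footer, byte-stable for fixed input.
#'
#' @param x an `lm_mrm`.
#' @return character vector of report lines.
#' @export
format_regression <- function(x) {
  co <- x$coefficients
  star <- ifelse(co$significant, "*", "")
  pv <- ifelse(co$p_value < 2e-16, "< 2e-16", sprintf("%.6g", co$p_value))
  lines <- c(
    sprintf("Step-wise multiple regression model (criterion: %s)", x$criterion),
    "",
    "Residuals:",
    sprintf("  Min %.5f  1Q %.5f  Median %.5f  3Q %.5f  Max %.5f",
            x$residual_quantiles[1], x$residual_quantiles[2],
            x$residual_quantiles[3], x$residual_quantiles[4],
            x$residual_quantiles[5]),
    "",
    sprintf("%-40s %12s %12s %9s %10s %s", "Variables/Coefficients", "Estimate",
            "Std. Error", "t value", "Pr(>|t|)", "Sig."),
    sprintf("%-40s %12.5f %12.6f %9.3f %10s %s", co$term, co$estimate,
            co$std_error, co$t_value, pv, star),
    "",
    sprintf("n: %d. Multiple R-squared: %.4f. Adjusted R-squared: %.4f.",
            x$n, x$r_squared, x$adj_r_squared),
    sprintf("Residual standard error: %.5g on %d degrees of freedom.",
            x$sigma, x$df_residual)
  )
  if (!is.null(x$fstatistic))
    lines <- c(lines, sprintf("F-statistic: %.4g on %d and %d DF.",
                              x$fstatistic$value, x$fstatistic$df1,
                              x$fstatistic$df2))
  if (length(x$dropped_constant))
    lines <- c(lines, sprintf("Dropped constant predictors: %s",
                              paste(x$dropped_constant, collapse = ", ")))
  if (length(x$aliased))
    lines <- c(lines, sprintf("Aliased (rank-deficient) terms: %s",
                              paste(x$aliased, collapse = ", ")))
  c(lines, sprintf("Significance codes: * < %.3f", x$alpha))
}

#' @export
print.lm_mrm <- function(x, ...) {
  cat(format_regression(x), sep = "\n")
  invisible(x)
}

#' Write a regression result as JSON
#'
#' @param x an `lm_mrm` or `lm_linear_fit`.
#' @param path output path.
#' @export
write_regression_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}

#' Simple linear regression between two per-hexagon metrics
#'
#' Ordinary least squares of `y` on `x`; R-squared is the squared Pearson
#' correlation, the p value the two-sided slope t test.
#'
#' @param x predictor values (e.g. per-hexagon IDC).
#' @param y response values (e.g. per-hexagon ESC).
#' @return an `lm_linear_fit`: list `slope, intercept, r_squared, p_value, n`.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) invalid_argument("linear_fit needs at least 3 finite pairs")
  if (stats::var(x) == 0) invalid_argument("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = n
  ), class = "lm_linear_fit")
}

#' @export
print.lm_linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: y = %.4f x + %.4f, R-squared %.4f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}
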