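#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1 at one digit), the
#' convention used in printed area tables, unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with a class so tests can assert on error type
abort_lm <- function(msg, class) {
  stop(structure(
    class = c(class, "landmetab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

invalid_argument <- function(msg) abort_lm(msg, "landmetab_invalid_argument")
validation_error <- function(msg) abort_lm(msg, "landmetab_validation_error")
empty_result <- function(msg) abort_lm(msg, "landmetab_empty_result")
invalid_configuration <- function(msg) abort_lm(msg, "landmetab_invalid_configuration")

`%||%` <- function(a, b) if (is.null(a)) b else a

# polygon area by the shoelace formula; vertices as two-column matrix, open ring
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clip of a convex polygon to an axis-aligned rectangle
clip_polygon_rect <- function(xy, xmin, xmax, ymin, ymax) {
  clip_edge <- function(poly, inside, intersect) {
    if (nrow(poly) == 0) return(poly)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      cur <- poly[i, ]
      prv <- poly[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, dim) {
    t <- (val - p[dim]) / (q[dim] - p[dim])
    p + t * (q - p)
  }
  poly <- xy
  poly <- clip_edge(poly, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  poly <- clip_edge(poly, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  poly <- clip_edge(poly, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  poly <- clip_edge(poly, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  poly
}
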