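#' Per-hexagon Shannon heterogeneity H'
#'
#' Normalised Shannon entropy over habitat categories: covers are grouped by
#' the legend's `habitat_category` (urban/industrial/degraded classes share a
#' "no habitat" category), proportions are re-tallied per category, and
#' `H' = -sum(p log p) / log(J)` with J the configured number of categories,
#' so H' is 0 for a single-category hexagon and 1 when all J categories are
#' present in equal shares. The log base cancels under the normalisation.
#'
#' @param composition an `lm_composition`.
#' @param legend an `lm_legend` whose `habitat_category` covers the classes
#'   to include; classes with `NA` habitat are ignored.
#' @param J number of habitat categories to normalise by; defaults to the
#'   number of distinct categories in the legend. Must be >= 2.
#' @return data.frame `hex_id, hprime` (NA for excluded hexagons).
#' @export
shannon <- function(composition, legend, J = NULL) {
  cats <- legend$habitat_category[!is.na(legend$habitat_category)]
  J <- J %||% length(unique(cats))
  if (J < 2) invalid_configuration("Shannon needs at least 2 habitat categories")
  cls <- as.integer(colnames(composition$P))
  cat_of <- legend$habitat_category[match(cls, legend$code)]
  keep <- !is.na(cat_of)
  hprime <- rep(NA_real_, nrow(composition$P))
  Pk <- composition$P[, keep, drop = FALSE]
  fk <- factor(cat_of[keep], levels = unique(cat_of[keep]))
  for (h in seq_len(nrow(Pk))) {
    if (composition$excluded[h]) next
    p <- tapply(Pk[h, ], fk, sum)
    p <- p[!is.na(p) & p > 0]
    tot <- sum(p)
    if (tot <= 0) { hprime[h] <- 0; next }
    p <- p / tot
    hprime[h] <- -sum(p * log(p)) / log(J)
  }
  data.frame(hex_id = composition$hex_id, hprime = hprime)
}

#' Combined landscape complexity Le
#'
#' Weighted mean of pattern (H') and process (ECI rescaled to [0, 1]):
#' `Le = (a H' + b ECI/10) / (a + b)`. With a = b this is the plain average;
#' the weights stand in for the canonical coefficients orthogonalising the
#' two indices, which the source index family leaves to calibration.
#'
#' @param hprime H' value(s) in [0, 1].
#' @param eci ECI value(s) in [0, 10].
#' @param a,b positive weights (default 1, 1).
#' @return Le value(s) in [0, 1].
#' @export
landscape_complexity <- function(hprime, eci, a = 1, b = 1) {
  if (a <= 0 || b <= 0) invalid_argument("weights a and b must be positive")
  ok <- is.na(hprime) | (hprime >= -1e-9 & hprime <= 1 + 1e-9)
  if (!all(ok)) invalid_argument("hprime out of [0, 1]")
  ok <- is.na(eci) | (eci >= -1e-9 & eci <= 10 + 1e-9)
  if (!all(ok)) invalid_argument("eci out of [0, 10]")
  (a * hprime + b * eci / 10) / (a + b)
}

#' Intermediate Disturbance Complexity composite
#'
#' `IDC = Le * (1 - HANPP/100)`: landscape complexity discounted by the share
#' of potential production appropriated by society. Bounded in [0, 1].
#'
#' @param le Le value(s) in [0, 1].
#' @param hanpp_pct HANPP as percent of potential NPP, clamped upstream to
#'   [0, 100].
#' @return IDC value(s).
#' @export
idc <- function(le, hanpp_pct) {
  ok <- is.na(le) | (le >= -1e-9 & le <= 1 + 1e-9)
  if (!all(ok)) invalid_argument("le out of [0, 1]")
  ok <- is.na(hanpp_pct) | (hanpp_pct >= -1e-9 & hanpp_pct <= 100 + 1e-9)
  if (!all(ok)) invalid_argument("hanpp_pct out of [0, 100]")
  le * (1 - hanpp_pct / 100)
}

#' Classify hexagons into landscape-metabolic configurations
#'
#' Rule set mirroring the three observed configuration types: `anthropic`
#' for IDC inside the low band (default 0.05–0.3, the published bracket for
#' industrial-agriculture valley units); `natural` for IDC inside the
#' low-to-moderate band with natural covers dominating (> `natural_dominance`
#' of the hexagon); `mosaic` for IDC at or above the high threshold;
#' everything else `unclassified`.
#'
#' @param idc_values numeric IDC per hexagon.
#' @param natural_share share of natural covers (forest/seminatural + water
#'   typologies) per hexagon, in [0, 1].
#' @param anthropic_band `c(lo, hi)` for the anthropic IDC band.
#' @param natural_band `c(lo, hi)` for the natural IDC band.
#' @param mosaic_min minimum IDC for mosaics.
#' @param natural_dominance dominance threshold (default 0.5).
#' @return character vector of labels.
#' @export
classify_configuration <- function(idc_values, natural_share,
                                   anthropic_band = c(0.05, 0.3),
                                   natural_band = c(0.3, 0.5),
                                   mosaic_min = 0.5,
                                   natural_dominance = 0.5) {
  if (anthropic_band[2] > natural_band[1] + 1e-12 ||
      natural_band[2] > mosaic_min + 1e-12)
    invalid_configuration("configuration bands overlap")
  n <- length(idc_values)
  lab <- rep("unclassified", n)
  nat <- idc_values >= natural_band[1] & idc_values < natural_band[2] &
    natural_share > natural_dominance
  lab[!is.na(idc_values) & idc_values > anthropic_band[1] &
        idc_values < anthropic_band[2]] <- "anthropic"
  lab[!is.na(idc_values) & !is.na(natural_share) & nat] <- "natural"
  lab[!is.na(idc_values) & idc_values >= mosaic_min] <- "mosaic"
  lab[is.na(idc_values)] <- NA_character_
  lab
}

#' Share of natural covers per hexagon
#'
#' Natural covers are the `forest_seminatural` and `water` typologies.
#'
#' @param composition an `lm_composition`.
#' @param legend an `lm_legend`.
#' @return numeric share in [0, 1] per hexagon.
#' @export
natural_cover_share <- function(composition, legend) {
  cls <- as.integer(colnames(composition$P))
  typ <- legend$typology[match(cls, legend$code)]
  nat <- typ %in% c("forest_seminatural", "water")
  as.numeric(composition$P[, nat, drop = FALSE] %*% rep(1, sum(nat)))
}
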