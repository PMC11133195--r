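#' Per-class NPP table
#'
#' Potential (`npp0`), actual (`nppact`) and harvested (`npph`) net primary
#' production per land-cover class, in t C/ha/yr. Harvest cannot exceed
#' actual production; violations are rejected at load.
#'
#' @param class integer class codes.
#' @param npp0 potential NPP (> 0).
#' @param nppact actual NPP (>= 0).
#' @param npph harvested NPP (>= 0, <= nppact).
#' @return data.frame of class `lm_npp`.
#' @export
npp_table <- function(class, npp0, nppact, npph) {
  tb <- data.frame(class = as.integer(class), npp0 = as.numeric(npp0),
                   nppact = as.numeric(nppact), npph = as.numeric(npph))
  if (anyDuplicated(tb$class)) validation_error("duplicate NPP class codes")
  if (any(tb$npp0 <= 0)) validation_error("npp0 must be positive")
  if (any(tb$nppact < 0) || any(tb$npph < 0))
    validation_error("nppact and npph must be non-negative")
  bad <- tb$class[tb$npph > tb$nppact + 1e-12]
  if (length(bad))
    validation_error(sprintf("npph exceeds nppact for classes: %s",
                             paste(bad, collapse = ", ")))
  class(tb) <- c("lm_npp", "data.frame")
  tb
}

#' Read / write the NPP table CSV (`class,npp0_tC_ha,nppact_tC_ha,npph_tC_ha`)
#' @param path file path.
#' @export
read_npp <- function(path) {
  df <- utils::read.csv(path)
  npp_table(df$class, df$npp0_tC_ha, df$nppact_tC_ha, df$npph_tC_ha)
}

#' @rdname read_npp
#' @param npp an `lm_npp`.
#' @export
write_npp <- function(npp, path) {
  df <- data.frame(class = npp$class, npp0_tC_ha = npp$npp0,
                   nppact_tC_ha = npp$nppact, npph_tC_ha = npp$npph)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-class HANPP accounting
#'
#' `dNPP_lu = NPP_0 - NPP_act` (land-use-induced change, may be negative,
#' e.g. irrigated cropland out-producing the potential vegetation);
#' `HANPP = dNPP_lu + NPP_h`; `HANPP%` = 100 * HANPP / NPP_0, kept raw and
#' additionally clamped to [0, 100] for consumption by the IDC composite.
#'
#' @param npp an `lm_npp`.
#' @return data.frame of class `lm_hanpp`: `class, dnpp_lu, hanpp_tC_ha,
#'   hanpp_pct, hanpp_pct_clamped`.
#' @export
compute_hanpp_class <- function(npp) {
  if (any(npp$npp0 <= 0)) validation_error("npp0 must be positive")
  dnpp <- npp$npp0 - npp$nppact
  habs <- dnpp + npp$npph
  pct <- 100 * habs / npp$npp0
  out <- data.frame(class = npp$class, dnpp_lu = dnpp, hanpp_tC_ha = habs,
                    hanpp_pct = pct,
                    hanpp_pct_clamped = pmin(pmax(pct, 0), 100))
  class(out) <- c("lm_hanpp", "data.frame")
  out
}

#' Per-hexagon HANPP: composition-weighted class averages
#'
#' `HANPP_hex = sum_i w_i P_i` with `w_i` the proportion of land cover i in
#' the hexagon (the composition row) and `P_i` the class HANPP value.
#' Both the absolute (t C/ha) and clamped-percent aggregates are returned;
#' excluded hexagons carry NA.
#'
#' @param composition an `lm_composition`.
#' @param hanpp an `lm_hanpp` with a row for every class present.
#' @return data.frame `hex_id, hanpp_tC_ha, hanpp_pct`.
#' @export
hanpp_hex <- function(composition, hanpp) {
  cls <- as.integer(colnames(composition$P))
  i <- match(cls, hanpp$class)
  present <- colSums(composition$P[!composition$excluded, , drop = FALSE],
                     na.rm = TRUE) > 0
  if (any(is.na(i) & present))
    validation_error(sprintf("no HANPP row for classes: %s",
                             paste(cls[is.na(i) & present], collapse = ", ")))
  w_abs <- hanpp$hanpp_tC_ha[i]; w_pct <- hanpp$hanpp_pct_clamped[i]
  w_abs[is.na(w_abs)] <- 0; w_pct[is.na(w_pct)] <- 0
  out <- data.frame(
    hex_id = composition$hex_id,
    hanpp_tC_ha = as.numeric(composition$P %*% w_abs),
    hanpp_pct = as.numeric(composition$P %*% w_pct)
  )
  out$hanpp_tC_ha[composition$excluded] <- NA_real_
  out$hanpp_pct[composition$excluded] <- NA_real_
  out
}
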