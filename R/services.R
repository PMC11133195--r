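#' The 21-service CICES-derived catalogue
#'
#' Level-3 service codes grouped into the three sections used throughout
#' (provisioning, regulation and support, cultural), shipped as package data.
#'
#' @return data.frame `section, division, code, group`.
#' @export
service_catalog <- function() {
  path <- system.file("extdata", "cices_services.csv", package = "landmetab")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expert panel responses
#'
#' One row per (expert, service, cover): supply and demand scored on the
#' six-class Likert scale 0 (not relevant) … 5 (very high).
#'
#' @param expert_id expert identifiers.
#' @param service_code service codes (e.g. "2.3.5").
#' @param section service section: `provisioning`, `regulation_support`, or
#'   `cultural`.
#' @param cover integer land-cover class codes.
#' @param supply,demand integer scores in 0..5.
#' @return data.frame of class `lm_panel`.
#' @export
expert_responses <- function(expert_id, service_code, section, cover,
                             supply, demand) {
  ok_sec <- c("provisioning", "regulation_support", "cultural")
  df <- data.frame(expert_id = expert_id,
                   service_code = as.character(service_code),
                   section = as.character(section),
                   cover = as.integer(cover),
                   supply = as.integer(supply), demand = as.integer(demand),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$section), ok_sec)
  if (length(bad))
    validation_error(sprintf("unknown service sections: %s",
                             paste(bad, collapse = ", ")))
  if (any(!df$supply %in% 0:5) || any(!df$demand %in% 0:5))
    validation_error("supply/demand scores must be integers in 0..5")
  key <- paste(df$expert_id, df$service_code, df$cover)
  if (anyDuplicated(key))
    validation_error("duplicate (expert, service, cover) responses")
  class(df) <- c("lm_panel", "data.frame")
  df
}

#' Read / write expert responses CSV
#' (`expert_id,service_code,section,cover,supply,demand`)
#' @param path file path.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(service_code = "character"))
  expert_responses(df$expert_id, df$service_code, df$section, df$cover,
                   df$supply, df$demand)
}

#' @rdname read_panel
#' @param panel an `lm_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Average a panel into supply and demand matrices
#'
#' Arithmetic mean of every expert's score per (service, cover) cell, equal
#' weights, no trimming; the expert count per cell is recorded.
#'
#' @param panel an `lm_panel`.
#' @return an `lm_service_matrix`: list with `supply`, `demand` (service x
#'   cover matrices), `count`, `section` (named by service code).
#' @export
aggregate_panel <- function(panel) {
  services <- sort(unique(panel$service_code))
  covers <- sort(unique(panel$cover))
  fs <- factor(panel$service_code, levels = services)
  fc <- factor(panel$cover, levels = covers)
  S <- tapply(panel$supply, list(fs, fc), mean)
  D <- tapply(panel$demand, list(fs, fc), mean)
  n <- tapply(panel$supply, list(fs, fc), length)
  n[is.na(n)] <- 0L
  sec <- tapply(panel$section, fs, function(x) x[1])
  structure(list(supply = S, demand = D, count = n,
                 section = stats::setNames(as.character(sec), services)),
            class = "lm_service_matrix")
}

#' Ecosystem-service capacity of a (service, cover) cell
#'
#' Capacity = supply − demand on the Likert scale, in [-5, 5].
#'
#' @param S supply score(s) in [0, 5].
#' @param D demand score(s) in [0, 5].
#' @return capacity value(s).
#' @export
capacity <- function(S, D) {
  if (any(S < 0 | S > 5, na.rm = TRUE) || any(D < 0 | D > 5, na.rm = TRUE))
    invalid_argument("supply and demand scores must lie in [0, 5]")
  S - D
}

#' Per-cover ecosystem-service capacity ESC_i
#'
#' Mean capacity over the services scored for each cover (the mean keeps the
#' printed [-5, 5] range; `fun = "sum"` is available for sensitivity runs).
#'
#' @param matrix an `lm_service_matrix`.
#' @param fun `"mean"` (default) or `"sum"`.
#' @return named numeric vector, one entry per cover code.
#' @export
cover_capacity <- function(matrix, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  C <- capacity(matrix$supply, matrix$demand)
  empty <- colSums(!is.na(C)) == 0
  if (any(empty))
    validation_error(sprintf("covers with no scored services: %s",
                             paste(colnames(C)[empty], collapse = ", ")))
  f <- if (fun == "mean") function(x) mean(x, na.rm = TRUE)
       else function(x) sum(x, na.rm = TRUE)
  apply(C, 2, f)
}

#' Per-cover multifunctionality MF_i
#'
#' Breadth of service provision across the three sections: for each section,
#' the fraction of its services whose mean supply reaches `threshold`
#' (default 3, "medium"); MF_i is 5 times the mean of the three fractions,
#' hence in [0, 5] with 5 = every service of every section provided.
#'
#' @param matrix an `lm_service_matrix`.
#' @param threshold Likert supply threshold for counting a service (default 3).
#' @return named numeric vector, one entry per cover code.
#' @export
cover_multifunctionality <- function(matrix, threshold = 3) {
  secs <- c("provisioning", "regulation_support", "cultural")
  sec <- matrix$section[rownames(matrix$supply)]
  sizes <- table(factor(sec, levels = secs))
  if (any(sizes == 0))
    invalid_configuration(sprintf("empty service sections: %s",
                                  paste(secs[sizes == 0], collapse = ", ")))
  vapply(seq_len(ncol(matrix$supply)), function(j) {
    fr <- vapply(secs, function(s) {
      sup <- matrix$supply[sec == s, j]
      sup <- sup[!is.na(sup)]
      if (!length(sup)) return(0)
      sum(sup >= threshold) / sizes[[s]]
    }, numeric(1))
    5 * mean(fr)
  }, numeric(1)) |> stats::setNames(colnames(matrix$supply))
}

#' Per-hexagon ESC and MF: composition-weighted cover scores
#'
#' `ESC_j = sum_i ESC_i P_ij` and `MF_j = sum_i MF_i P_ij` — convex
#' combinations of the member-cover scores under each hexagon's composition.
#'
#' @param composition an `lm_composition`.
#' @param esc_i named numeric vector of per-cover capacities (names = codes).
#' @param mf_i named numeric vector of per-cover multifunctionality.
#' @return data.frame `hex_id, esc, mf` (NA for excluded hexagons).
#' @export
esc_hex <- function(composition, esc_i, mf_i) {
  cls <- colnames(composition$P)
  present <- colSums(composition$P[!composition$excluded, , drop = FALSE],
                     na.rm = TRUE) > 0
  miss <- cls[present & (!cls %in% names(esc_i) | !cls %in% names(mf_i))]
  if (length(miss))
    validation_error(sprintf("no cover score for classes: %s",
                             paste(miss, collapse = ", ")))
  e <- ifelse(cls %in% names(esc_i), esc_i[cls], 0)
  m <- ifelse(cls %in% names(mf_i), mf_i[cls], 0)
  out <- data.frame(hex_id = composition$hex_id,
                    esc = as.numeric(composition$P %*% e),
                    mf = as.numeric(composition$P %*% m))
  out$esc[composition$excluded] <- NA_real_
  out$mf[composition$excluded] <- NA_real_
  out
}
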