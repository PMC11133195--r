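#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' objects. All tuning parameters carry the documented defaults; `NULL`
#' means "use the package default" (affinity) or "skip the stage" (panel).
#'
#' @param raster land-cover raster: `lm_raster` or ESRI ASCII grid path.
#' @param legend legend: `lm_legend` or CSV path.
#' @param npp NPP table: `lm_npp` or CSV path.
#' @param affinity affinity matrix, CSV path, or NULL for [default_affinity()].
#' @param barriers barrier spec, CSV path, or NULL for none.
#' @param panel expert panel, CSV path, or NULL to skip the service stage.
#' @param cell_area hexagon area (ha, default 2000).
#' @param min_valid_fraction hexagon retention threshold (default 0.5).
#' @param shannon_J habitat-category count for H' (NULL = from legend).
#' @param le_a,le_b Le weights (default 1, 1).
#' @param mf_threshold Likert supply threshold for MF (default 3).
#' @param connectivity 4 or 8 (default 8).
#' @param base_cost base traversal cost (default 1).
#' @param exponent ECI_b exponent reading (default "ratio").
#' @param min_patch minimum source patch size in cells (default 1).
#' @param Xt_override fixed theoretical maximum cost, or NULL.
#' @param anthropic_band,natural_band,mosaic_min,natural_dominance
#'   configuration-classification bands (see [classify_configuration()]).
#' @param stepwise_criterion "AIC" or "pvalue".
#' @param seed RNG seed echoed into outputs (the pipeline itself is
#'   deterministic).
#' @param out_dir output directory, or NULL to skip writing.
#' @return a `run_config` list.
#' @export
run_config <- function(raster, legend, npp, affinity = NULL, barriers = NULL,
                       panel = NULL, cell_area = 2000,
                       min_valid_fraction = 0.5, shannon_J = NULL,
                       le_a = 1, le_b = 1, mf_threshold = 3,
                       connectivity = 8, base_cost = 1, exponent = "ratio",
                       min_patch = 1, Xt_override = NULL,
                       anthropic_band = c(0.05, 0.3),
                       natural_band = c(0.3, 0.5), mosaic_min = 0.5,
                       natural_dominance = 0.5,
                       stepwise_criterion = "AIC", seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' File-path fields are resolved relative to the YAML's directory.
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("raster", "legend", "npp", "affinity", "barriers", "panel")) {
    if (!is.null(y[[k]]) && is.character(y[[k]]) &&
        !file.exists(y[[k]]))
      y[[k]] <- file.path(base, y[[k]])
  }
  do.call(run_config, y)
}

#' Load and cross-validate all pipeline inputs
#'
#' Reads every configured input and validates the cross-references (raster
#' codes in the legend, NPP coverage, affinity area names, panel covers).
#' Failures are collected and reported together, not first-only.
#'
#' @param config a `run_config`.
#' @return list `raster, legend, npp, affinity, barriers, panel`.
#' @export
load_inputs <- function(config) {
  get_in <- function(x, reader) {
    if (is.null(x) || !is.character(x)) x else reader(x)
  }
  legend <- get_in(config$legend, read_legend)
  raster <- get_in(config$raster, read_ascii_grid)
  npp <- get_in(config$npp, read_npp)
  affinity <- get_in(config$affinity, read_affinity) %||% default_affinity()
  barriers <- get_in(config$barriers, read_barriers)
  panel <- get_in(config$panel, read_panel)

  errs <- character(0)
  codes <- unique(as.vector(raster$grid))
  codes <- codes[codes != raster$nodata]
  bad <- setdiff(codes, legend$code)
  if (length(bad))
    errs <- c(errs, sprintf("raster codes missing from legend: %s",
                            paste(sort(bad), collapse = ", ")))
  bad <- setdiff(codes, npp$class)
  if (length(bad))
    errs <- c(errs, sprintf("raster codes missing from NPP table: %s",
                            paste(sort(bad), collapse = ", ")))
  fa <- unique(legend$functional_area[!is.na(legend$functional_area)])
  bad <- setdiff(fa, rownames(affinity))
  if (length(bad))
    errs <- c(errs, sprintf("functional areas missing from affinity matrix: %s",
                            paste(bad, collapse = ", ")))
  if (!is.null(panel)) {
    bad <- setdiff(codes, unique(panel$cover))
    if (length(bad))
      errs <- c(errs, sprintf("raster codes unscored by the expert panel: %s",
                              paste(sort(bad), collapse = ", ")))
  }
  if (length(errs))
    validation_error(paste(c("input validation failed:", errs),
                           collapse = "\n  - "))
  list(raster = raster, legend = legend, npp = npp, affinity = affinity,
       barriers = barriers, panel = panel)
}

#' Run the full landscape-metabolism pipeline
#'
#' Stages, in order: hexagon grid and composition, Shannon H', ECI, HANPP,
#' Le and IDC, configuration classification, ESC/MF (skipped with a warning
#' when no panel is configured), stepwise regression of IDC on cover
#' proportions and the IDC–ESC linear fit. Deterministic for a fixed
#' config.
#'
#' @param config a `run_config`.
#' @return list with `metrics` (per-hexagon data.frame `hex_id, hprime, eci,
#'   eci_rescaled, hanpp_tC_ha, hanpp_pct, le, idc, natural_share,
#'   config_label, esc, mf`), `grid`, `composition`, `area_table`, `mrm`,
#'   `esc_fit`, `cover_scores`, `params`.
#' @export
run_pipeline <- function(config) {
  inp <- load_inputs(config)
  raster <- inp$raster; legend <- inp$legend

  ext <- c(raster$origin[1],
           raster$origin[1] + ncol(raster$grid) * raster$cell_size,
           raster$origin[2] - nrow(raster$grid) * raster$cell_size,
           raster$origin[2])
  grid <- build_hex_grid(ext, config$cell_area)
  comp <- compute_composition(raster, grid, config$min_valid_fraction)

  hp <- shannon(comp, legend, J = config$shannon_J)
  eci_res <- compute_eci(raster, legend, inp$affinity, inp$barriers,
                         grid = grid, connectivity = config$connectivity,
                         base_cost = config$base_cost,
                         exponent = config$exponent,
                         min_patch = config$min_patch,
                         Xt_override = config$Xt_override)
  hn <- hanpp_hex(comp, compute_hanpp_class(inp$npp))

  metrics <- data.frame(hex_id = grid$hex_id,
                        hprime = hp$hprime,
                        eci = eci_res$hex$eci,
                        eci_rescaled = eci_res$hex$eci_rescaled,
                        hanpp_tC_ha = hn$hanpp_tC_ha,
                        hanpp_pct = hn$hanpp_pct)
  metrics$le <- landscape_complexity(metrics$hprime, metrics$eci,
                                     config$le_a, config$le_b)
  metrics$idc <- idc(metrics$le, metrics$hanpp_pct)
  metrics$natural_share <- natural_cover_share(comp, legend)
  metrics$config_label <- classify_configuration(
    metrics$idc, metrics$natural_share,
    anthropic_band = config$anthropic_band,
    natural_band = config$natural_band,
    mosaic_min = config$mosaic_min,
    natural_dominance = config$natural_dominance)

  cover_scores <- NULL; esc_fit <- NULL
  if (!is.null(inp$panel)) {
    sm <- aggregate_panel(inp$panel)
    esc_i <- cover_capacity(sm)
    mf_i <- cover_multifunctionality(sm, config$mf_threshold)
    sv <- esc_hex(comp, esc_i, mf_i)
    metrics$esc <- sv$esc; metrics$mf <- sv$mf
    cover_scores <- data.frame(cover = as.integer(names(esc_i)),
                               esc = as.numeric(esc_i),
                               mf = as.numeric(mf_i[names(esc_i)]))
  } else {
    warning("no expert panel configured; ESC/MF stage skipped")
    metrics$esc <- NA_real_; metrics$mf <- NA_real_
  }

  ok <- !comp$excluded & !is.na(metrics$idc)
  mrm <- stepwise_mrm(metrics$idc[ok],
                      as.data.frame(comp$P[ok, , drop = FALSE]),
                      criterion = config$stepwise_criterion)
  if (!is.null(inp$panel))
    esc_fit <- linear_fit(metrics$idc[ok], metrics$esc[ok])

  at <- summarize_areas(raster, legend)
  out <- list(metrics = metrics, grid = grid, composition = comp,
              area_table = at, mrm = mrm, esc_fit = esc_fit,
              cover_scores = cover_scores,
              params = config[setdiff(names(config), c("raster", "legend",
                                                       "npp", "affinity",
                                                       "barriers", "panel"))])
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' `hex_metrics.csv`, `hexgrid.geojson` (metrics as feature properties),
#' `area_table.csv`, `regression.txt`/`regression.json`, `cover_scores.csv`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(dir, "hex_metrics.csv"),
                   row.names = FALSE)
  write_hex_geojson(result$grid, file.path(dir, "hexgrid.geojson"),
                    properties = result$metrics[, -1])
  write_area_table(result$area_table, file.path(dir, "area_table.csv"))
  writeLines(format_regression(result$mrm), file.path(dir, "regression.txt"))
  write_regression_json(result$mrm, file.path(dir, "regression.json"))
  if (!is.null(result$cover_scores))
    utils::write.csv(result$cover_scores, file.path(dir, "cover_scores.csv"),
                     row.names = FALSE)
  invisible(dir)
}
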