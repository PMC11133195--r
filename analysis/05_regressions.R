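#!/usr/bin/env Rscript
# Stage 5 - statistical analyses.
#
# Step-wise multiple regression of per-hexagon IDC on the cover-class
# proportions (AIC-driven bidirectional selection over the full legend) and
# the linear IDC-ESC relationship across hexagons.

suppressPackageStartupMessages(library(landmetab))

hexfile <- file.path("results", "pipeline", "hex_metrics.csv")
if (!file.exists(hexfile))
  stop("run analysis/03_landscape_metrics.R first", call. = FALSE)

out <- file.path("results", "regressions")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

inp <- file.path("results", "inputs")
raster <- read_ascii_grid(file.path(inp, "landcover.asc"))
legend <- read_legend(file.path(inp, "legend.csv"))
metrics <- utils::read.csv(hexfile)

ext <- c(raster$origin[1],
         raster$origin[1] + ncol(raster$grid) * raster$cell_size,
         raster$origin[2] - nrow(raster$grid) * raster$cell_size,
         raster$origin[2])
grid <- build_hex_grid(ext, 2000)
comp <- compute_composition(raster, grid)
keep <- !comp$excluded

P <- as.data.frame(comp$P[keep, , drop = FALSE])
names(P) <- legend$name[match(as.integer(names(P)), legend$code)]
fit <- stepwise_mrm(metrics$idc[keep], P)
writeLines(format_regression(fit), file.path(out, "stepwise_idc.txt"))
write_regression_json(fit, file.path(out, "stepwise_idc.json"))
cat(format_regression(fit), sep = "\n")
cat("\n")

lf <- linear_fit(metrics$idc[keep], metrics$esc[keep])
cat(sprintf("IDC-ESC relationship: ESC = %.3f IDC %+.3f (R-squared %.3f, p %.2g, n %d)\n",
            lf$slope, lf$intercept, lf$r_squared, lf$p_value, lf$n))
write_regression_json(lf, file.path(out, "idc_esc_fit.json"))
cat(sprintf("reports written to %s\n", out))
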