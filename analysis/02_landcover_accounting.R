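#!/usr/bin/env Rscript
# Stage 2 - land-cover accounting.
#
# Two area tables: (i) the published per-class areas rolled up into their
# groups, with percents on the published 1,004,000 ha study-area base, and
# (ii) the same accounting computed from the synthetic raster of stage 1.

suppressPackageStartupMessages(library(landmetab))

out <- file.path("results", "accounting")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
legend <- ucrv_legend()

published <- area_table(table1_areas(), legend, percent_base = 1004000)
write_area_table(published, file.path(out, "area_table_published.csv"))
g <- area_groups(published)
cat("published accounting (percent base 1,004,000 ha):\n")
for (nm in c("Total others", "Total primary forest", "Total permanent crops",
             "Total agricultural mosaics", "Total urban and industrial areas")) {
  cat(sprintf("  %-35s %12.2f ha  %5.1f%%\n", nm,
              g$area_ha[g$reclass == nm],
              round_half_up(g$percent[g$reclass == nm], 1)))
}
cat(sprintf("  sugarcane class share: %.1f%%\n",
            round_half_up(published$percent[published$code == 11], 1)))

asc <- file.path("results", "inputs", "landcover.asc")
if (file.exists(asc)) {
  r <- read_ascii_grid(asc)
  synth <- summarize_areas(r, legend)
  write_area_table(synth, file.path(out, "area_table_synthetic.csv"))
  cat(sprintf("synthetic raster: %.0f ha across %d classes\n",
              attr(synth, "total_ha"), nrow(synth)))
} else {
  cat("note: run 01_simulate_landscape.R first for the synthetic table\n")
}
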