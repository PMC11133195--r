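#!/usr/bin/env Rscript
# Stage 1 - simulate the study inputs.
#
# Generates the synthetic landscape (60 x 100 cells at 500 m, three zonation
# bands: sugarcane-dominated valley, mixed-mosaic slope, natural highland),
# the per-class NPP table and the 27-expert Likert panel, and writes them as
# plain-text inputs for the later stages.

suppressPackageStartupMessages(library(landmetab))

out <- file.path("results", "inputs")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- ucrv_scenario(seed = 1)
landscape <- generate_landscape(scenario)
legend <- ucrv_legend()
npp <- generate_npp(legend, seed = 2)
panel <- generate_expert_panel(legend, n_experts = 27, seed = 3)

write_ascii_grid(landscape, file.path(out, "landcover.asc"))
write_legend(legend, file.path(out, "legend.csv"))
write_npp(npp, file.path(out, "npp.csv"))
write_affinity(default_affinity(), file.path(out, "affinity.csv"))
write_panel(panel, file.path(out, "expert_panel.csv"))

tab <- table(landscape$grid)
cat(sprintf("landscape: %d x %d cells, %d classes, dominant class %s (%.1f%%)\n",
            nrow(landscape$grid), ncol(landscape$grid), length(tab),
            names(which.max(tab)), 100 * max(tab) / sum(tab)))
cat(sprintf("NPP table: %d classes; expert panel: %d responses from %d experts\n",
            nrow(npp), nrow(panel), length(unique(panel$expert_id))))
cat(sprintf("inputs written to %s\n", out))
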