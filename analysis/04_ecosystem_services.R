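#!/usr/bin/env Rscript
# Stage 4 - ecosystem-service capacity and multifunctionality.
#
# Aggregates the 27-expert Likert panel into supply/demand matrices,
# derives per-cover capacity (ESC, supply minus demand averaged over the 21
# services) and multifunctionality (MF, breadth of provision across the
# provisioning / regulation / cultural sections), and reports the cover
# ranking driving the per-hexagon scores of stage 3.

suppressPackageStartupMessages(library(landmetab))

inp <- file.path("results", "inputs")
if (!file.exists(file.path(inp, "expert_panel.csv")))
  stop("run analysis/01_simulate_landscape.R first", call. = FALSE)

out <- file.path("results", "services")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read_panel(file.path(inp, "expert_panel.csv"))
legend <- read_legend(file.path(inp, "legend.csv"))
sm <- aggregate_panel(panel)
esc_i <- cover_capacity(sm)
mf_i <- cover_multifunctionality(sm, threshold = 3)

scores <- data.frame(
  cover = as.integer(names(esc_i)),
  name = legend$name[match(as.integer(names(esc_i)), legend$code)],
  esc = round(as.numeric(esc_i), 3),
  mf = round(as.numeric(mf_i[names(esc_i)]), 3)
)
scores <- scores[order(-scores$esc), ]
utils::write.csv(scores, file.path(out, "cover_scores.csv"), row.names = FALSE)

cat(sprintf("panel: %d experts x %d services x %d covers\n",
            length(unique(panel$expert_id)), nrow(sm$supply), ncol(sm$supply)))
cat("top and bottom covers by capacity (ESC in [-5, 5], MF in [0, 5]):\n")
print(utils::head(scores, 4), row.names = FALSE)
print(utils::tail(scores, 4), row.names = FALSE)
cat(sprintf("cover scores written to %s\n", file.path(out, "cover_scores.csv")))
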