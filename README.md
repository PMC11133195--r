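# landmetab

Landscape-metabolism metrics for metropolitan green infrastructure.

`landmetab` turns a categorical land-cover raster plus agricultural-metabolism
tables into per-hexagon indicators of landscape pattern, process and human
disturbance, for regions — such as the tropical-Andean Cauca River valley that
motivated the method — where a metropolis is embedded in a mosaic of
monocultures, biocultural agricultural landscapes and natural highlands. It is
aimed at landscape ecologists and land-use planners who want the whole chain,
from raster to regression table, reproducible in code.

## The model

The study area is tessellated into equal-area hexagons (2,000 ha by default).
For each hexagon *j* with cover proportions *P<sub>ij</sub>*:

- **Heterogeneity** — normalised Shannon entropy over habitat categories:
  *H′ = −Σ p log p / log J* ∈ [0, 1].
- **Connectivity (ECI)** — for each functional ecological area *b* (forest,
  shrubland, grassland/paramo, agroforestry mosaic, crops, pastures,
  sugarcane), a friction surface is built from an affinity matrix and
  anthropogenic-barrier impacts, least accumulated costs *X<sub>i</sub>* are
  computed by Dijkstra on the cell graph, and
  *ECI<sub>b</sub> = 10 − 9·[ln(1+X<sub>i</sub>)/ln(1+X<sub>t</sub>)]³*;
  the total *ECI = Σ ECI<sub>b</sub> / m* ranges over roughly 0–10.
- **HANPP** — human appropriation of net primary production per class,
  *HANPP = ΔNPP<sub>Lu</sub> + NPP<sub>h</sub>* with
  *ΔNPP<sub>Lu</sub> = NPP₀ − NPP<sub>act</sub>* (t C/ha/yr and % of NPP₀),
  aggregated as *HANPP<sub>hex</sub> = Σ w<sub>i</sub>P<sub>i</sub>*.
- **Intermediate Disturbance Complexity** —
  *Le = (aH′ + b·ECI/10)/(a+b)* and *IDC = Le·(1 − HANPP/100)* ∈ [0, 1];
  hexagons are classed into anthropic / natural / mosaic landscape-metabolic
  configurations by IDC bands and natural-cover dominance.
- **Ecosystem services** — a Likert expert panel (0–5) is averaged into
  supply/demand matrices over 21 CICES-derived services; capacity
  *ESC = S − D* ∈ [−5, 5] and multifunctionality *MF* ∈ [0, 5] per cover are
  weighted into *ESC<sub>j</sub> = Σ ESC<sub>i</sub>P<sub>ij</sub>* (and the
  analogue for MF).
- **Statistics** — deterministic bidirectional stepwise (AIC) regression of
  IDC on the cover proportions, and the linear IDC–ESC fit.

A seeded neutral-landscape generator (modified random clusters over a
valley/slope/highland zonation, with linear river/road barriers), synthetic
NPP tables and synthetic expert panels make the whole pipeline runnable with
no external geodata.

## Worked example

```r
library(landmetab)

legend <- ucrv_legend()
raster <- generate_landscape(ucrv_scenario(seed = 1))
cfg <- run_config(raster = raster, legend = legend,
                  npp = generate_npp(legend, seed = 2),
                  panel = generate_expert_panel(legend, seed = 3))
res <- run_pipeline(cfg)
aggregate(res$metrics[, c("hprime", "eci", "hanpp_pct", "idc", "esc")],
          list(band = hex_band(res$grid, ucrv_scenario(seed = 1))),
          mean, na.rm = TRUE)
#>       band    hprime      eci hanpp_pct       idc       esc
#> 1 highland 0.4318530 9.131436  5.567035 0.6331618  2.945345
#> 2    slope 0.4784631 9.559232 32.942433 0.4808008  1.595244
#> 3   valley 0.3148366 8.437148 65.214065 0.2048269 -2.402652
res$esc_fit
#> linear fit: y = 11.8255 x + -4.4955, R-squared 0.9011, p 6.44e-39, n 76
```

The monoculture valley has the highest human appropriation (65% of potential
production), the lowest heterogeneity, connectivity and IDC, and a negative
service capacity; the mosaic mid-slopes sit at intermediate disturbance with
the strong positive IDC–ESC relationship the model predicts.

The same sequence, with all tables written under `results/`, is available as
numbered drivers:

```sh
Rscript analysis/01_simulate_landscape.R
Rscript analysis/02_landcover_accounting.R
Rscript analysis/03_landscape_metrics.R
Rscript analysis/04_ecosystem_services.R
Rscript analysis/05_regressions.R
```

## Layout

- `R/` — all computation (accounting, hexagon grid, connectivity, HANPP,
  IDC, services, regression, simulation, pipeline).
- `analysis/` — the numbered workflow drivers above.
- `vignettes/landscape-metabolism.Rmd` — the methods vignette: model
  assumptions, parameter defaults, numerical choices, limitations.
- `inst/extdata/` — the published land-cover/area table and the 21-service
  catalogue as CSV.
- `tests/testthat/` — unit, property and acceptance tests against
  independent oracles (exhaustive path enumeration, per-cell tallies,
  closed-form least squares).
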