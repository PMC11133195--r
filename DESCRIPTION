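Package: landmetab
Title: Landscape-Metabolism Metrics for Metropolitan Green Infrastructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes landscape-metabolism indicators for a categorical
    land-cover map partitioned into equal-area hexagonal analysis units:
    Shannon heterogeneity (H'), a cost-distance Ecological Connectivity
    Index (ECI), Human Appropriation of Net Primary Production (HANPP),
    the Intermediate Disturbance Complexity composite (IDC), and
    expert-matrix ecosystem-service capacity (ESC) and multifunctionality
    (MF), together with the stepwise and linear regressions linking them.
    Includes a seeded neutral-landscape generator (modified random
    clusters over a valley/slope/highland zonation), synthetic NPP tables
    and Likert expert panels so the whole pipeline runs without external
    geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
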