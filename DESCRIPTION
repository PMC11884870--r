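Package: prosocca
Title: Brain Markers of Prosocial Behavior via Sparse Multi-Set Canonical
    Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A data-driven pipeline linking behavior in fifteen economic games
    to multimodal brain features. Provides a payoff-aware synthetic-study
    generator with a planted latent prosociality trait, confound
    residualization, connectome graph metrics (clustering coefficient, local
    efficiency, nodal path length, degree, betweenness) under cost-efficiency
    thresholding, homotopic interhemispheric connectivity, PCA dimensionality
    reduction, sparse multiple canonical correlation analysis with
    permutation-based penalty selection and significance testing, and canonical
    cross-loading summaries with per-metric-class confidence intervals and
    top-fraction region maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
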