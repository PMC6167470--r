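Package: gcbrainbow
Title: Stochastic Germinal-Centre Simulation of Multi-Colour Brainbow Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates germinal-centre (GC) B-cell reactions as a stochastic,
    individual-cell dark-zone/light-zone model with shape-space somatic
    hypermutation and affinity-dependent selection, and overlays brainbow
    (Confetti) multi-colour staining: founder staining, one-shot staining and
    tamoxifen-induced staining with exponentially decaying recombination
    probability. Provides clone and lineage tracking, the dominance statistics
    used to interpret multi-colour data (clonal, lineage and colour dominance,
    colour density, and their product), and cohort-level analyses (Pearson
    correlations with Fisher-transform confidence intervals, staining-threshold,
    staining-time, stained-fraction and colour-scheme sweeps) for designing
    lineage-tracing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
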