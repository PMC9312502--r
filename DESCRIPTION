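Package: benthirr
Title: Community Bioirrigation Potential (BIPc) for Benthic Macrofauna
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the trait-based community bioirrigation potential index
    (BIPc) of soft-sediment macrofauna, with separate trait scores for
    diffusion- and advection-dominated sediment systems, alongside the
    reference community bioturbation potential (BPc). Provides grain-size
    based sediment-system classification, coverage diagnostics, depth-layer
    and vertical-profile index variants, temporal comparisons via ANOVA with
    Tukey HSD compact letter displays, collinearity-screened random-forest
    spatial mapping with permutation importance and rank-correlation
    validation, bivariate hotspot overlays of index rasters, correlation
    suites against tracer-irrigation and solute-flux measurements, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
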