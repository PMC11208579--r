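Package: acarange
Title: Host-Range Expansion Modelling for Permanently Parasitic Mites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to model host-range expansion in permanently parasitic
    mammalian mites. Builds a 13-predictor feature table per mite species
    from host-parasite associations, host traits, geographic ranges and a
    host phylogeny; fits natural-spline logistic regressions under five
    class-imbalance strategies (baseline, publication-count weighting,
    down-sampling, up-sampling, and positive-unlabeled learning with an
    AdaSampling loop); evaluates models with repeated stratified
    cross-validation and a holdout set; forecasts a multi-host risk group
    with per-host-order enrichment; and fits a companion host-host
    mite-sharing model on phylogenetic distance and geographic overlap.
    A seeded synthetic-data generator with known ground truth supports
    end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    e1071,
    pROC,
    jsonlite,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
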