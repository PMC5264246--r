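Package: balancetrees
Title: Balance Trees for Compositional Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compositional analysis of microbial count tables with balances:
    isometric log-ratio (ILR) transforms driven by bifurcating trees,
    niche-driven tree construction by UPGMA clustering of abundance-weighted
    mean gradient values (e.g. mean pH), ordinary least-squares and linear
    mixed-effects regression on balances with Bonferroni correction, back
    transformation of fitted balances to predicted community proportions, and
    simulation generators for unimodal gradient communities, blooming-species
    false-discovery experiments and patient-structured repeated measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
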