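Package: decaylab
Title: Quantitative Analysis of Experimental Decay (Taphonomy) Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of experimental decay
    (taphonomy) experiments with destructive sampling, modelled on decay
    studies of soft-bodied invertebrates such as velvet worms
    (Onychophora). Aggregates specimen-level three-state condition scores
    (pristine/decaying/lost) into ordinal five-state decay trajectories,
    extracts decay milestones and builds decay-rank tables with a
    hierarchical tie-break; computes synapomorphic ranks of anatomical
    characters on rooted phylogenetic hypotheses and runs the
    decay-rank versus synapomorphic-rank Spearman test battery used to
    detect stemward slippage, with exact-permutation, Monte Carlo and
    t-approximation p-values; fits percent-change morphometric
    regressions with F-tests of slope; tests slope heterogeneity of
    body-region decay trajectories and runs onset-of-loss ANOVA with
    Tukey HSD; and includes a seeded synthetic decay-experiment
    generator so every stage of the pipeline is testable without
    original specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
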