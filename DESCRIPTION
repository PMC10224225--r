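Package: gutplaque
Title: Multi-Omics Integration of Gut Microbiota, Inflammation, and
    Metabolites with Carotid Artery Plaque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline linking gut metagenomic species
    and functional enzymes, serum proteomic inflammatory markers, and
    plasma metabolites to carotid artery plaque. Implements compositional
    transforms (centered log-ratio, rank-based inverse-normal),
    prevalence/abundance feature filtering, omics quality-control filters
    with half-minimum imputation, alpha diversity and weighted UniFrac
    distances, covariate-adjusted logistic and linear association screens
    with Benjamini-Hochberg false-discovery control, a two-class LDA
    effect-size differential-abundance screen, a covariate-adjusted
    pairwise log-ratio W statistic, PLS-DA inflammation profiling with
    per-component outcome models, hypergeometric enzyme-category
    enrichment, mutual-adjustment species selection, and a weighted
    gut-microbiota score. A synthetic multi-omics cohort generator with a
    planted ground-truth record supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
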