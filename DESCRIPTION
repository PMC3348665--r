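Package: prmt
Title: Predicted Relative Metabolomic Turnover from Metagenomic Enzyme Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts relative metabolomic turnover (PRMT) of a microbial
    community from enzyme-function (EC number) read counts of multiple
    metagenomes. Parses and filters a reaction catalog, builds the
    metabolite-by-enzyme Environmental Metabolome Matrix (EMM) with
    currency-metabolite exclusion and reversible-reaction cancellation,
    quantile-normalizes enzyme activity counts across samples, and scores
    each metabolite's change in consumption/production capacity against a
    reference community. Includes a permutation/resampling null for calling
    strong Pearson correlations between scores and environmental parameters
    or taxon abundances, extraction of taxon-correlated metabolic
    subnetworks, Cytoscape-compatible SIF/GraphML export, and a synthetic
    fixture generator with planted signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
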