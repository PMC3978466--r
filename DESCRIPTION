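Package: emlandscape
Title: Mapping the Extracellular-Milieu Transcriptional Landscape with
    Preranked Gene Set Enrichment Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for two-strain, multi-timepoint expression
    studies: genes are ranked between consecutive timepoints with the SAM
    relative-difference statistic, gene sets are scored by preranked gene set
    enrichment analysis with permutation p-values, normalized enrichment
    scores, false discovery rates and leading-edge extraction, strain-parallel
    alterations are subtracted, extracellular-milieu (EM)-related and
    EM-associated gene sets are qualified through Gene Ontology ancestry,
    leading-edge-overlap networks are clustered with the Markov cluster
    algorithm and collapsed into metanode gene clouds, and the dependence of
    biological themes on susceptibility loci is quantified with one-way ANOVA
    and Tukey post hoc tests. Includes a synthetic-data generator with planted
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
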