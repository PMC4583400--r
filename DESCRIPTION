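Package: barcodegap
Title: DNA Barcode Species Delimitation from COI Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for operational taxonomic unit (OTU) delimitation from
    aligned mitochondrial COI barcode sequences. Implements Kimura
    2-parameter and p-distances with pairwise deletion of missing data,
    haplotype collapsing, neighbor-joining and UPGMA trees with bootstrap
    support, single-linkage objective clustering across distance thresholds,
    automatic barcode gap discovery (ABGD-style recursive partitioning),
    the single-threshold generalized mixed Yule-coalescent (GMYC) model,
    a maximum-likelihood Poisson tree process (PTP) delimiter, comparison
    of molecular partitions against morphospecies labels (name propagation,
    discrimination rate, divergence summaries), and a coalescent simulator
    of species-structured barcode datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
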