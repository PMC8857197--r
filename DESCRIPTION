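Package: grnforge
Title: Curation, Inference and Assessment of Bacterial Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assemble evidence-graded transcriptional regulatory
    networks from heterogeneous curated sources, to infer new regulatory
    interactions from transcription-factor binding sites (position weight
    matrix construction, exact p-value scanning, regulon extension,
    cross-species regulog transfer) and from expression compendia (CLR and
    MRNET with transcription-factor-constrained causality), to integrate
    ranked predictions into community networks by average rank, to assess
    predictions against gold standards (AUPR, AUROC, MCC, Simpson overlap),
    to profile and compare network structure (power-law degree-distribution
    fits, clustering-coefficient scaling, structural-property clustering,
    pairwise graph dissimilarity), and to classify genes into system-level
    components (global regulators, modules, intermodular genes and basal
    machinery) with the natural decomposition approach. A seeded synthetic
    generator produces scale-free networks, linear-model expression data,
    genomes with planted binding sites and orthologous organism pairs so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    MASS,
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
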