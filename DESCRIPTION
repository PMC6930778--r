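Package: megrank
Title: Network-Weighted Screening of Monotonically Expressed Genes in
    Longitudinal Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies monotonically expressed genes (MEGs) in longitudinal
    treatment-response expression data. Cross-sectional case/control
    differential expression is assessed with empirical-Bayes moderated
    t-tests and Benjamini-Hochberg false-discovery-rate control; the
    resulting gene set is re-weighted per sample by solving the GeneRank
    linear system over a gene-interaction network; weighted values are then
    screened across time points with Kruskal-Wallis tests and a monotone
    pattern filter, and each MEG is classified as a "good response" gene
    (monotone direction discordant with its disease-versus-control
    direction) or a "bad response" gene (concordant). Includes a synthetic
    data generator with planted truth for validation, lossless TSV readers
    and writers, and an end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
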