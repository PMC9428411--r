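Package: diffgrn
Title: Differential Gene Regulatory Network Analysis of Sex-Biased Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of condition-specific gene regulation from bulk
    expression data, built around the comparison of male and female regulatory
    networks in the developing brain. Provides expression preprocessing
    (variance filtering, sex-chromosome removal, outlier detection, batch
    adjustment), soft-thresholded co-expression modules with GSEA-style module
    activity scoring, message-passing inference of bipartite transcription
    factor to gene regulatory networks from a motif prior, protein-protein
    interactions and co-expression, Barber bipartite modularity community
    detection, differential-modularity comparison of two condition networks
    with interquartile-range driver extraction, hypergeometric
    over-representation analysis and permutation-based gene-set enrichment,
    plus a synthetic-data generator with planted, sex-specific regulatory
    rewiring for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
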