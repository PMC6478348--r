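Package: exonml
Title: Exon-Level Differential Usage and Unsupervised Machine Learning for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exon-level analysis toolkit for two-condition RNA-Seq
    experiments. Provides a simplified negative-binomial GLM test for
    differential exon usage with Benjamini-Hochberg FDR control, principal
    component analysis with observation contributions and cos2 diagnostics,
    cluster-tendency assessment (Hopkins statistic, VAT ordering), cluster
    number selection (wss elbow, silhouette, gap statistic), multi-restart
    k-means, fuzzy c-means, hierarchical clustering on principal components
    with k-means consolidation, a self-organizing map, and a permutation-null
    gene-set enrichment engine that separates true from false pathway
    enrichment using size-matched random gene lists. Ships a fully specified
    synthetic-data generator and a printed miRNA host-exon feature table so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    cluster,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
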