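Package: readclust
Title: Two-Stage Clustering of Short Metagenomic Reads Using Cross-Sample
    Coverage Covariation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters short metagenomic reads by genome of origin in two
    stages. A local stage builds a read overlap graph from shared canonical
    k-mers or minimizers and partitions it with deterministic label
    propagation, yielding many small, pure read clusters. A global stage
    estimates each cluster's per-sample sequencing coverage from
    representative k-mers drawn near the peak of its k-mer frequency
    spectrum, links clusters whose coverage profiles covary across samples
    (cosine similarity above a threshold), and merges them by weighted label
    propagation. Includes a truth-labeled multi-sample community simulator
    and purity/completeness evaluation of clusterings against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
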