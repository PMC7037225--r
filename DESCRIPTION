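Package: upstreamx
Title: Upstream Analysis of Gene Expression: From Differential Expression
    to Master Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the three-stage "upstream analysis" used to infer
    candidate master regulators from a gene-expression experiment:
    (i) negative-binomial differential expression calling on a read-count
    matrix with logFC and p-value cut-offs; (ii) MATCH-style position
    weight matrix scanning of promoter sequences, Fisher-exact enrichment
    of binding sites in differentially expressed ("Yes") versus background
    ("No") promoter sets with Benjamini-Hochberg correction, and a genetic
    algorithm search for composite cis-regulatory modules of up to ten
    motifs in a 200-300 bp window scored by Wilcoxon separation;
    (iii) a bounded reverse breadth-first search of a directed signaling
    network that scores each node by its distance-decayed reach of the
    active transcription factors, with a permutation null yielding
    Z-scores and an empirical FDR. Also provides direction-matched
    comparison of master-regulator tables across treatments (Venn counts,
    common-to-all intersection, category annotation summaries), simulators
    for counts, promoters and networks with planted ground truth, and a
    deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    edgeR
Config/testthat/edition: 3
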