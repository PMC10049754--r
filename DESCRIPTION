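Package: celltyper
Title: Marker-Based Cell-Type Annotation for Clustered Transcriptomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates clusters of cells (or bulk samples) with cell-type
    labels by testing cluster-specific differentially expressed marker genes
    against tissue-filtered cell-marker gene-set databases. Two statistical
    engines are provided: preranked gene-set enrichment analysis with a
    gene-permutation null, and a one-sided Fisher's exact
    (hypergeometric) over-representation test with expression-score-aware
    ranking. Both report Benjamini-Hochberg adjusted p-values per cluster
    and yield hard (single best) and soft (top-k) classifications, together
    with plot-ready dot-plot and bar-plot summary tables. A synthetic-data
    module generates marker databases and cluster marker tables with known
    ground truth so that per-cell annotation accuracy can be evaluated
    end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
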