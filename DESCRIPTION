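Package: gptide
Title: Gaussian-Process Time-Course Differential Expression for the
    Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting temporally differentially expressed genes
    between two conditions of a developmental RNA-seq time course using
    exact Gaussian-process regression on variance-stabilized abundances and
    a marginal-likelihood-ratio test, followed by k-means trajectory
    clustering with silhouette-based selection of the cluster number,
    microRNA seed-match and RNA-element motif enrichment in 3' UTRs,
    position weight matrix enrichment in promoters, fractional-weight
    quantification of repetitive loci from multi-mapping alignments, and
    short-insert fragment inference from adapter read-through in paired-end
    reads. A synthetic-data generator produces every input the pipeline
    consumes, with planted ground truth, so the full analysis is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
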