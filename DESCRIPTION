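Package: thpnet
Title: Chemical Space Networks and Multi-Query Similarity Searching for
    Tumor-Homing Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-science workflow for discovering tumor-homing peptides
    (THPs) by repurposing antimicrobial peptides. Builds chemical space
    networks (CSNs) over peptide sets from min-max normalized Euclidean
    distances on physicochemical descriptors, detects communities with the
    Louvain method, ranks peptides by network centrality (weighted degree,
    harmonic, betweenness, community hub-bridge), extracts non-redundant
    scaffold representatives by centrality-ranked greedy removal at a
    Smith-Waterman local-identity cutoff, and assembles the survivors into
    multi-query similarity searching models (SSMs) that classify candidate
    peptides by group fusion (MAX-SIM) of BLOSUM62 local-alignment identity
    scores. Includes retrospective benchmarking statistics (accuracy, kappa,
    sensitivity, specificity, precision, Matthews correlation coefficient,
    false accept rate, Friedman rank tests), a hierarchical prospective
    screening pipeline, and a seeded synthetic peptide-family generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
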