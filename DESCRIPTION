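Package: orthoseek
Title: Iterative Homolog and Ortholog Discovery with Identity and
    Domain-Architecture Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers homologous and orthologous proteins from one or more
    query sequences by iterative sequence and profile search. Candidate hits
    are admitted through two filters: a length-dependent percent-identity
    threshold (the Rost twilight-zone curve with a tunable stringency offset)
    and a protein-length filter that uses length as a proxy for domain
    architecture, trimming extra terminal domains. Orthologs are classified by
    reciprocal best hits against the source proteome. Includes a local
    Smith-Waterman alignment engine with position-specific scoring matrix
    (PSSM) profile search, an adapter for precomputed BLAST tabular hits,
    sensitivity/specificity/REQ evaluation with coordinate-wise parameter
    optimization, functional-annotation frequency summaries, and a synthetic
    protein-family simulator that provides labelled benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
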