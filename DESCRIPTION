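Package: icrevo
Title: Evolution and Transcriptomic Impact of Genomic Imprinting Control Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the sequence evolution and the early-embryo
    transcriptome impact of genomic imprinting control regions (ICRs).
    Implements CpG composition statistics (observed/expected CpG ratio,
    promoter CpG-class assignment), a strand-symmetric trinucleotide
    context-dependent substitution model with exact Gillespie simulation
    on a phylogeny, composite-likelihood estimation of context-dependent
    substitution rates and branch lengths with block-bootstrap confidence
    intervals, Fitch-parsimony substitution counting as an independent
    estimator, classification of expression changes across fully imprinted,
    maternal-imprint-free and imprint-free embryo epigenotypes, and
    hypergeometric gene-ontology overrepresentation analysis. A synthetic
    data module generates sequence, expression and annotation datasets with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
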