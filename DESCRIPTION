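Package: kmerclass
Title: Environmental Source Classification of Metagenomic Samples from
    k-mer Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies whole-metagenome sequencing samples to their
    environmental class of origin (e.g. the city a surface swab was taken
    in) using canonical k-mer "fingerprint" databases. Builds counted
    k-mer databases from reference samples, filters infrequent k-mers at
    the sample or class level, subtracts a host (human) k-mer database,
    concatenates read pairs with a marker symbol, scores every query read
    against each class by the fraction of its nucleotides covered by
    shared k-mers, gates reads by a similarity threshold and a maximum
    class count, accumulates per-class points under simple, fractional or
    weighted schemes, and classifies each sample to the class of largest
    normalized similarity. Includes leave-one-out cross-validation with
    confusion matrices and precision/recall metrics, mutual-similarity
    matrices with row normalization and graph-based clustering, a
    deterministic synthetic-metagenome generator for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
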