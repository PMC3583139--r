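Package: paleohom
Title: Ancestral-State Relatedness Tests for Deep Protein Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probing protein homology beyond the twilight zone of
    sequence identity. Implements Fitch-parsimony reconstruction of ancestral
    nucleotide ambiguity sets on gene trees, a structure/sequence alignment
    consensus procedure for selecting test regions, screening rules for
    homology-search hits, and Fitch's statistical test comparing the observed
    mutation distance between two ancestral states with its expectation under
    a random site-pairing null. A Jukes-Cantor gene-family simulator supports
    type-I error and power calibration of the test, and a pipeline driver ties
    the stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
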