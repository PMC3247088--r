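Package: privrisk
Title: Re-Identification Risk Assessment for Person-Level Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying re-identification risk in person-level
    (e.g. health) microdata under adversaries with approximate knowledge.
    Implements k-anonymity and its edit-distance generalisation
    (k-l-anonymity) with an indexed Levenshtein neighborhood search,
    quasi-identifier uniqueness profiling, a seeded simulator of an
    attacker holding a perturbed identifier, and a cross-source profile
    linkage attack (attribution, rule-based inference, and aggregation of
    profiles into dossiers via strong/weak evidence). Includes generators
    for synthetic populations, phonebooks, and multi-source profile sets
    with ground-truth identity maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
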