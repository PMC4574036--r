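Package: recoder
Title: Semi-Automatic Recoding of Biomedical Data Values to Coding Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches free-text or locally coded biomedical data values (phenotypes,
    physical activities, clinical symptoms) to a target coding system or ontology.
    Candidate concepts are retrieved from an inverted index with TF-IDF cosine
    scoring and fuzzy term expansion, then re-scored with a normalized character
    bigram (Sorensen-Dice) similarity expressed as a percentage, so that a single
    cut-off can auto-accept confident matches. Includes a curation loop that learns
    accepted matches as new synonyms, precision/recall-at-rank evaluation against
    gold standards, cut-off calibration tables, a seeded synthetic corpus generator,
    and a command-line interface. Reads OBO ontologies and delimited or Excel
    codebooks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    readxl,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
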