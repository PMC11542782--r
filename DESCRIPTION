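Package: crfmapr
Title: Siamese-Network Mapping of eCRF Field Metadata to SDTM Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns a low-dimensional metric embedding of electronic case
    report form (eCRF) field metadata (form and field identifiers, pre-text
    and post-text) with a Siamese recurrent network, so that fields mapping
    to the same SDTM (Study Data Tabulation Model) variable cluster
    together, and suggests mapping targets with an exact k-nearest-neighbour
    classifier over the learned embeddings. Includes leakage-safe stratified
    splitting and contrastive pair generation, holdout and cross-validated
    evaluation with accuracy and macro-F1, a TF-IDF plus gradient-boosted
    tree baseline, and a synthetic annotated-CRF corpus generator so the
    whole pipeline can be trained and tested without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xml2,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
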