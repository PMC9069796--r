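Package: polyrasch
Title: Rasch Rating Scale Analysis for Polytomous Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint maximum likelihood estimation of the Rasch rating scale
    model for ordered-category questionnaire data, with the full diagnostic
    workflow used in instrument validation studies: Infit/Outfit mean-square
    fit statistics with iterative misfit-item removal, rating-scale category
    diagnostics including Andrich threshold ordering, unidimensionality and
    local-independence checks via principal components of standardized
    residuals, separation indices and reliabilities for items and persons,
    differential item functioning by binary group, and text Wright
    item-person maps. Ships the EAT-26 instrument definition with its
    classical 0-3 scoring rule and a seeded response simulator with known
    generating parameters for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
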