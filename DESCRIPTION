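Package: herbsub
Title: Literature-Based Discovery of Herbal Alternatives for Drugs with
    Prominent Side Effects
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks western drugs by a "replaceable" score computed from
    drug/side-effect and drug/indication co-occurrence link weights in
    annotated scientific abstracts, and ranks traditional Chinese medicine
    herbs as alternatives for a selected drug via a substitutability score
    combining prescription dosage proportions with side-effect/indication
    term intersections in Chinese indication text. Includes classical
    dose-unit normalization (liang/qian/fen), toxicity (oral LD50) and
    half-life evaluation of selected drugs, oral-bioavailability and
    drug-likeness filtering of herb-ingredient-target-disease graphs, and a
    seeded synthetic-data generator with planted structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
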