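Package: parentese
Title: Infant-Directed Emotional Prosody Detection and Caregiver-Infant
    Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational analysis of early caregiver-infant
    interaction from coded home-video material: synthesis of labelled audio
    corpora and full interaction studies with known ground truth, extraction
    of segmental (MFCC) and supra-segmental (pitch, energy, duration)
    acoustic features, a two-stream Gaussian-mixture detector of parentese
    (infant-directed emotional prosody) with weighted score fusion and exact
    binomial evaluation, caregiver-to-infant response bi-gram extraction
    within a 3-second window with meta-behaviour aggregation, and binomial
    mixed-effects models of infant response probability with child-level
    random intercepts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
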