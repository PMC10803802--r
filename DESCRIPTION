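Package: drgkit
Title: Diagnosis-Related Group Prediction from Discharge Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for predicting Medicare Severity Diagnosis-Related
    Groups (MS-DRGs) from the free text of hospital discharge summaries.
    Provides catalog handling for the MS-DRG code system, including
    dissection of DRG codes into base-DRG and complication/comorbidity
    (CC/MCC) components and the inverse mapping rule; harmonization of DRG
    codes assigned under different annual MS-DRG versions to a single
    target version via title normalization and fuzzy matching with a
    manual-review escape hatch; corpus preparation
    (brief-hospital-course extraction, quality filtering, stratified
    train/test splitting, tokenization); backbone-agnostic single-label
    and two-label classification with last-token logits, cross-entropy
    losses, a low-rank adapter contract and reference backbones for
    desk-scale experiments; an evaluation harness with top-k accuracy,
    macro/micro F1 and AUC, and bootstrap standard deviations; and a
    synthetic-data generator producing catalogs and corpora with the
    long-tailed class structure of real DRG data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
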