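Package: hfcdss
Title: Hybrid Expert and Machine-Learned Decision Trees for Heart Failure
    Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: White-box clinical decision support for heart failure
    phenotyping by left ventricular ejection fraction (HFrEF, HFmrEF,
    HFpEF, no-HF).  Provides an expert-authored clinical knowledge model
    as an executable decision tree, CART-style rule induction with Gini
    splitting and native missing-value routing, and a hybridization step
    that grafts learned subtrees onto the expert tree at the points where
    patient records fall through (notably "Not Available" paths for
    missing attributes).  Trees are serialized as JSON knowledge models,
    flattened into mutually exclusive production rules for a shareable
    rule base, and executed with full explanation traces.  Includes a
    seeded synthetic cohort generator parameterized from published
    per-phenotype summary statistics, and an evaluation suite (confusion
    matrices, concordance, sensitivity/specificity, subgroup and
    cohort-summary analyses) for comparing expert, machine-learned and
    hybrid engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
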