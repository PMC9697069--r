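Package: pipntools
Title: Pharmacovigilance and Preclinical Quantification of Paclitaxel-Induced
    Peripheral Neuropathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two analytic arms of paclitaxel-induced peripheral
    neuropathy (PIPN) research. The pharmacovigilance arm builds case/non-case
    2x2 contingency tables from FAERS-style spontaneous adverse-event reports
    and computes reporting odds ratios with Woolf 95 percent confidence
    intervals and chi-squared tests with a configurable Yates continuity rule,
    plus a count-inversion oracle that recovers unpublished cell counts from
    printed ROR/CI values. The preclinical arm estimates 50 percent mechanical
    withdrawal thresholds from von Frey up-down staircases and computes nerve
    fiber morphometry (circularity, g-ratio, myelin thickness) from polygon
    geometry or integer label masks. Synthetic-data generators with known
    ground truth drive all three pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
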