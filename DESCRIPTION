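Package: ldctscreen
Title: Nodule Management Rule Engine for LDCT Lung Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, auditable implementation of the Modified
    I-ELCAP Croatia decision rules for managing pulmonary nodules found on
    low-dose CT (LDCT) lung cancer screening scans. Classifies baseline,
    annual/biennial and interim follow-up scans into negative,
    semi-positive and positive categories with recall intervals and
    referral actions, each decision carrying an auditable rule code.
    Includes sphere volumetry and volume-doubling-time (VDT) utilities,
    program eligibility checks (age, pack-years, quit window, exclusion
    criteria), scanner quality-control validation against minimum
    technical requirements with per-scan and cumulative radiation dose
    tracking, and a synthetic-cohort microsimulator that exercises the
    full multi-round screening protocol. Data-frame in, tibble out
    throughout; no images are processed, only measurements.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
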