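Package: trialmatchr
Title: Comparing Clinical-Trial Participants with Matched Nonparticipants in
    Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the generalizability of clinical trials with
    electronic health record (EHR) data in an OMOP-style layout. The package
    selects trial participants by locating an index condition occurrence near
    each person's trial status date (with a prior-year reassurance
    requirement), draws matched nonparticipants by repeated exact matching on
    index condition, calendar month, and prior-year visit count, screens
    covariate imbalance with standardized differences at the 0.1 cutoff, and
    scans covariate-by-trial-characteristic associations with chi-squared or
    Fisher exact tests under a per-domain Bonferroni correction. A linked
    synthetic EHR, enrollment-report, and trial-metadata generator with known
    ground truth makes every stage testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
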