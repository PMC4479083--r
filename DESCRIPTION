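Package: serialdex
Title: Serial Tumor Gene Expression Analysis for Neoadjuvant Response and
    Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serial (pretreatment, early on-treatment,
    and surgical) tumor gene expression profiles from neoadjuvant chemotherapy
    studies. Provides print-batch residualization, probe-to-gene collapsing,
    paired and two-group permutation t-tests with Benjamini-Hochberg false
    discovery rate control, nearest-centroid molecular subtype assignment with
    paired concordance, per-gene Cox proportional-hazards screening against
    recurrence-free survival with Kaplan-Meier illustration, and Fisher exact
    gene-set overrepresentation. A fully documented synthetic-cohort generator
    with planted treatment, response and hazard signals makes every stage
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    survival,
    tibble,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
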