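Package: meningiomics
Title: Downstream Somatic Genomics Analyses for Meningioma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level downstream analyses for somatic genomic studies of
    meningioma, with an emphasis on high-grade (WHO grade II-III) disease.
    Provides mutation burden and substitution-spectrum statistics, arm-level
    somatic copy-number alteration calling and percent-genome-disrupted
    metrics, driver co-occurrence testing and a binomial power model for
    recurrently mutated gene detection, multi-sample heterogeneity
    partitioning and recurrence phylogenetics, complex-rearrangement
    decomposition with double-strand-break repair mechanism classification,
    and neoantigen composite-affinity scoring with a simplified cancer cell
    fraction model. A seeded synthetic tumor-evolution cohort generator with
    full ground-truth tables makes every stage testable without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
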