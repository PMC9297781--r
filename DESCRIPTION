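Package: fragmrd
Title: Fragment-Length Scoring and Tumour-Informed Variant Tracking for
    ctDNA Minimal Residual Disease Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects minimal residual disease (MRD) in postoperative plasma
    circulating tumour DNA (ctDNA) from hybrid-capture sequencing data by
    combining cell-free DNA (cfDNA) fragment-length analysis with
    tumour-informed variant tracking. Implements a bootstrapped log2
    density-ratio fragmentation score per fragment length, aggregated to a
    patient-level score (FS) over one million sampled fragments and to a
    variant-level score (VFS) over the reads supporting a variant;
    compartment-based germline/CHIP filtering and trackable-variant MRD
    calling with grid-search cut-off optimisation; a combined classifier
    evaluated by 20-times repeated 10-fold cross-validation with
    majority-vote calls, confusion-matrix and survival (Kaplan-Meier,
    log-rank) evaluation; a bootstrap simulation of adjuvant-chemotherapy
    benefit per predicted group; and a synthetic cfDNA cohort generator so
    the full pipeline can be exercised without patient data.
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
    Rsamtools,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
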