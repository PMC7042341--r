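Package: neofrag
Title: Calling Caspase-Fragmented Neoantigen Candidates from SILAC
    GeLC-MS and Deconvolving Pooled T-Cell Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Target-discovery toolkit for non-mutated neoantigen candidates
    in apoptotic tumour cells. Calls fragmented proteins from SILAC
    (stable isotope labelling by amino acids in cell culture) GeLC-MS
    quantitation by comparing gel-derived apparent molecular weight with the
    theoretical weight of the intact protein; matches heavy/light isotope
    peak pairs; designs overlapping 20-mer peptide libraries around
    MS-identified sequences and arranges them in a two-of-N pool matrix with
    deconvolution of pool-level T-cell positives; summarises cytokine
    response magnitude, responder fold changes and PD-1 kinetics across
    treatment time points; and relates CD8 response levels to overall
    survival by median split with Kaplan-Meier and log-rank comparison.
    Includes a seeded synthetic-data generator for proteomes with
    caspase-type fragments, label-swap SILAC replicates and patient cohorts,
    so the whole pipeline is testable without patient or raw MS data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
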