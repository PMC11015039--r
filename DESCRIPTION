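Package: repeatgain
Title: Somatic Repeat Instability Metrics from Capillary Fragment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies somatic CAG-repeat instability from capillary
    electrophoresis fragment analysis. Reads GeneMapper-style peak tables,
    calibrates fragment sizes to repeat units against per-run standards of
    known repeat length, and computes height-weighted instability metrics:
    modal repeat, weighted mean repeat length within a window around the
    modal peak, average repeat gain versus baseline, and repeat gain per
    week from a through-origin fit. Includes clone-wise vehicle
    normalization with Welch t-test contrasts, an 85 percent-rule zygosity
    caller for CRISPR amplicon editing outcomes, a splice-junction
    saturation-mutagenesis screen with a pluggable splice scorer, and a
    synthetic electropherogram generator (repeat-population drift, PCR
    stutter, size-dependent signal bias) used as the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    optparse,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
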