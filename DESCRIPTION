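Package: tede
Title: Testing Direct Effects of Genetic Instruments in Mendelian
    Randomization and TWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Goodness-of-fit tests for instrumental-variable analyses that
    use GWAS summary statistics. Implements score-based (TEDE-Sc) and
    adaptive sum-of-powered-scores (TEDE-aSPU) tests for the presence of
    direct SNP-to-outcome effects (horizontal pleiotropy), applicable to
    both independent instruments (Mendelian randomization) and
    LD-correlated instruments (transcriptome-wide association studies),
    together with the classical comparators Cochran's Q, MR-Egger and
    LD-aware MR-Egger. Sufficient cross-product moments are reconstructed
    from marginal summary statistics plus an LD reference panel, so no
    individual-level data are required. A simulation engine generates
    two-sample summary statistics under configurable pleiotropy scenarios
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
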