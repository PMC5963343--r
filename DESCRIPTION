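Package: ctquant
Title: Relative Quantification of Transcript Isoforms from qPCR Ct Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-time PCR relative quantification of transcript
    isoforms using the delta-delta-Ct method with variance bounds obtained by
    evaluating 2^-ddCt at ddCt plus and minus its standard deviation, averaging
    over two reference genes, and calling significant expression changes with a
    0.5 / 1.5 fold-change rule on both the point estimate and the relevant
    bound. Includes amplification-efficiency standard curves, RNA-stability
    quality control (RIN filtering and degradation time-courses), clinical
    cohort stratification by age at disease onset and disease duration with
    Welch t-tests and expression-covariate regression, and a synthetic Ct-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
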