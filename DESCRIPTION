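Package: isqc
Title: Near Real-Time Quality Control for Internal-Standardised LC-HRMS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quality control for liquid chromatography high-resolution
    mass spectrometry acquisitions that carry isotopically labelled internal
    standards. Extracts per-run peak height, retention time and mass error for
    each internal standard from mzML/mzXML files, corrects stored retention
    times by the median drift observed in blanks, applies rolling univariate
    control limits against 60-day medians, and runs multivariate statistical
    process control (PCA with Hotelling's T-squared and squared prediction
    error on pairwise internal-standard ratios) trained on recent in-control
    runs. Includes DDA MS2 library matching by binned cosine similarity, a
    CSV-backed results store with alert reports, a batch simulator with
    injectable instrument faults for end-to-end testing, and a command-line
    pipeline for folder watching and retrospective reanalysis.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
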