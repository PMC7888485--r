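Package: fcreliab
Title: Test-Retest Reliability of Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the test-retest reliability of functional
    connectivity matrices derived from parcellated resting-state fMRI
    timeseries. Implements per-run preprocessing (optional global signal
    regression, zero-phase high-pass filtering, motion scrubbing, run
    concatenation), session-wise Pearson connectomes, vectorized edge-wise and
    network-wise ICC(3,1) with F-based confidence intervals and reliability
    binning, absolute and relative threshold sweeps with the ratio of
    consistently retained edges, rank-based comparison tests, a reliability
    sample-size calculator, and a synthetic-cohort generator with known
    ground-truth reliability structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
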