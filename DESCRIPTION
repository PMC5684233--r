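Package: decoyFDR
Title: Decoy-Based and Empirical-Bayes False Discovery Rate Estimation
    for Spectral Library Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Significance estimation for MS/MS spectral-library annotation
    in untargeted metabolomics. Implements three decoy spectral-library
    constructions (naive fragment resampling, a conditional spectrum-based
    sampler, and fragmentation-tree re-rooting), separated target-decoy
    false discovery rate and q-value estimation with correction for the
    percentage of incorrect targets (PIT), an empirical-Bayes two-component
    mixture model of search scores fitted by expectation maximization, and
    a synthetic benchmark harness for assessing the calibration of the
    resulting q-values. Reads and writes spectra in MassBank record format
    and MGF, and fragmentation trees in a DOT dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
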