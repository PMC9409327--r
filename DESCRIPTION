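Package: hrvkit
Title: Heart Rate Variability Analysis from Beat-Annotated RR Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heart rate variability (HRV) analysis of short-term
    (20 minute) resting recordings: ectopic-beat editing and moving-window
    outlier filtering of RR interval series, the standard time-domain and
    geometric panel (SDNN, SDANN, SDNNi, RMSSD, NNx/pNNx, HRV triangular
    index, TINN), Welch-periodogram frequency-domain measures (VLF/LF/HF
    band powers, normalized powers, LF/HF ratio, band peak frequencies),
    and non-linear measures (Poincare SD1/SD2, sample entropy, detrended
    fluctuation analysis alpha1/alpha2).  A synthetic RR-series generator
    with controlled autonomic spectral structure and injectable ectopy, and
    a three-arm pre/post cohort simulator, allow the whole pipeline and the
    accompanying randomized-trial statistics (paired within-group tests,
    ANCOVA with age and baseline covariates, Sidak post hoc adjustment) to
    be exercised without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car,
    withr,
    optparse
Config/testthat/edition: 3
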