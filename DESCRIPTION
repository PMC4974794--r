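Package: agreeCI
Title: Chance-Corrected Inter-Rater Agreement with Bootstrap Confidence
    Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of Fleiss' K and Krippendorff's alpha for
    categorical ratings by two or more raters, including nominal and
    ordinal distance metrics and principled handling of missing ratings
    via the coincidence matrix. Provides the asymptotic confidence
    interval for Fleiss' K, subject-resampling percentile bootstrap
    intervals for both coefficients, and Krippendorff's original
    coincidence-matrix bootstrap for comparison. A Monte-Carlo engine
    simulates multi-rater rating studies with controllable true
    agreement and missing-completely-at-random deletion, and reports
    percentage bias and empirical coverage probability per coefficient
    and interval method.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
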