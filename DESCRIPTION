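Package: brachybed
Title: Biologically Effective Dose for Heterogeneous HDR Brachytherapy Dose Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear-quadratic biologically effective dose (BED) calculations for
    multi-fraction high-dose-rate (HDR) balloon brachytherapy, accounting for the
    strongly nonuniform dose distribution in the target volume. Provides
    differential and cumulative dose-volume histogram (DVH) containers with CSV
    input/output, conventional and DVH-weighted survival-averaged BED, per-fraction
    BED and interfraction-variation totals with numerically stable log-domain
    survival averaging, a seeded generator of balloon-applicator-like synthetic
    dose distributions, and a cohort pipeline comparing constant-case against
    interfraction-variation BED and heterogeneity-corrected against conventional
    BED across clinical endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
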