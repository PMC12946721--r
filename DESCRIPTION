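Package: mrmediate
Title: Two-Sample Mendelian Randomisation and Two-Step Mediation for GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Riley", "Carver", email = "rcarver@example.org",
           role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomisation (MR)
    and two-step MR mediation analysis on GWAS summary statistics.  Includes
    reading, validation and harmonisation of summary-statistics tables;
    instrument selection (significance thresholding with fallback, greedy LD
    clumping, outcome-association filtering, F-statistic and Steiger
    directionality filters); Wald-ratio, inverse-variance-weighted and
    MR-Egger estimators with Cochran's Q and Steiger sensitivity statistics;
    the MR-PRESSO parametric-resampling global, outlier and distortion tests;
    multivariable MR by weighted least squares; delta-method mediation
    decomposition (total, direct and indirect effects with mediated
    proportion); Benjamini-Hochberg screening with risk/protective
    classification; and a ground-truth synthetic GWAS triplet generator for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
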