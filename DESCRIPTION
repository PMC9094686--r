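Package: batvr
Title: Quantification of Behavioral Avoidance in Immersive Virtual Reality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immersive virtual-reality behavioral
    avoidance sessions. Computes the readouts of three VR tasks -- a
    behavioral search task (minimum stimulus distance, glances, body
    orientation), a forced-choice task (cost-weighted avoidance score over
    ten path segments), and an approach task (time to touch, path thirds,
    hand acceleration changes) -- from motion-tracking, gaze/pupil, and
    RR-interval streams. Includes pupillometry preprocessing (moving-median
    MAD outlier removal, interpolation, resampling, unit rescaling), glance
    segmentation with gap merging, windowed RR aggregation, a statistical
    layer (mixed repeated-measures ANOVA with partial and generalized
    eta-squared, nonparametric tests with Cohen's U3, Glass' delta, partial
    Spearman correlations, Bonferroni thresholds), and a synthetic-cohort
    generator driven by a latent spider-aversion parameter so every stage is
    testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
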