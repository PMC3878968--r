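Package: ktmb
Title: Distribution-Free Tests for Non-Decreasing Ordered Alternatives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rank-based tests for the non-decreasing ordered alternative in a
    completely randomized design with k >= 3 independent groups. Implements the
    KTMB test, whose statistic counts correctly placed observations (fixed
    points of the within-tuple rank permutation) summed over all k-tuplets,
    together with the Jonckheere-Terpstra (JT), modified JT (MJT),
    Terpstra-Magel (TM) and Spearman-kernel (KTP) comparators. Provides exact
    small-sample null distributions by enumeration of equally likely rank
    partitions, exact null moments for arbitrary designs via a tie-pattern
    covariance decomposition, seeded Monte Carlo moments, one-sided
    asymptotic-normal inference, and a log-F location-shift simulation engine
    for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
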