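Package: icedstab
Title: Longitudinal Stability of Repeated Measures via Intra-Class Effect
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the longitudinal stability (long-interval test-retest
    reliability) of repeated measurements by decomposing two-timepoint
    covariance into between-subjects and error variance components with a
    maximum-likelihood covariance-structure model. Provides intraclass
    correlations at the single-measure (ICC) and construct (ICC2) level with
    profile-likelihood confidence intervals, multigroup model comparisons
    (comparative fit index differences) that localise stability differences to
    between-subjects or error variance across testing sites or scanner
    manufacturers, batch stability maps over brain regions with rank-order
    stability (Shrout-Fleiss ICC(2,1)/ICC(3,1)) and lobe aggregation,
    design-planning calculators (required repeated measures, Spearman
    attenuation, correlation power), and a synthetic multi-site two-timepoint
    data generator with known variance components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
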