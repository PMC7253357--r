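Package: genemeta
Title: Genotype-Count Meta-Analysis for Case-Control Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysing case-control genetic association studies
    supplied as per-study genotype counts. Builds exposure-by-outcome 2x2
    tables under dominant, recessive and allelic genetic models, estimates
    per-study log odds ratios with Woolf variances, pools them with
    inverse-variance and Mantel-Haenszel fixed-effects and
    DerSimonian-Laird random-effects models, quantifies heterogeneity
    (Cochran's Q, I-squared), tests Hardy-Weinberg equilibrium, diagnoses
    publication bias (funnel data, Egger regression, Duval-Tweedie
    trim-and-fill) and runs leave-one-out and cumulative-by-year
    analyses. Ships a transcription of the eight BDNF Val66Met smoking
    persistence cohorts as a validated fixture, and a simulator of
    Hardy-Weinberg case-control cohorts with a known dominant-model odds
    ratio for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
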