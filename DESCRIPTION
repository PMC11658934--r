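Package: sibsr
Title: Sibling Sex Ratios, Socioeconomic Status and the Trivers-Willard
    Hypothesis
Version: 0.1.0
Authors@R:
    person("sibsr", "maintainers", email = "sibsr@example.org",
           role = c("aut", "cre"))
Description: Tools for testing the Trivers-Willard hypothesis on
    retrospective questionnaire data: a synthetic questionnaire-population
    generator with ground truth, exact-key family record linkage with
    recall/precision scoring, staged cohort exclusion cascades with
    per-step accounting, family and family-subunit sex-ratio extraction,
    self-contained quasi-Poisson and binomial GLM machinery (IRLS,
    forward-Helmert and sum contrasts, type-3 Wald tests, estimated
    marginal means, FDR-adjusted pairwise contrasts), and the two headline
    analyses: a sex-by-status model of reproductive success and a
    100-replicate balanced-resampling analysis of offspring sex ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
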