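Package: tvadual
Title: TVA Psychometric Modelling of Masked Dual-Feature Report Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models report accuracy in backward-masked letter identification
    and localization as a psychometric function of exposure duration, based on
    Bundesen's Theory of Visual Attention (TVA). Provides maximum-likelihood
    estimation of the temporal perception threshold (t0) and visual processing
    speed (v) from per-duration binomial counts, a stochastic-independence
    analysis of joint location/identity report outcomes, and the group-level
    inferential layer: paired and one-sample t tests with Cohen's d_z, JZS
    Bayes factors, 2x2 repeated-measures ANOVA with generalized eta squared,
    Holm-corrected post-hoc tests, and Cousineau-Morey within-subject
    confidence intervals. A synthetic trial generator emulates dual-report and
    blocked-report masking designs, including an optional coupling between the
    two features' encoding events for sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
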