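Package: votcp
Title: Categorical Perception Scoring and Mediation Analysis for Voice Onset Time Continua
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of categorical perception of voicing
    contrasts in children, built around a /d/-/t/ voice onset time (VOT)
    continuum. Provides seeded constructors of balanced identification,
    AX discrimination, letter-report and single-letter designs; a synthetic
    cohort generator for dyslexic and control children with dissociated
    phoneme-awareness and visual-attention-span deficits and a planted
    mediation structure; signal-detection scoring of observed and predicted
    discrimination (d-prime with log-linear correction), logistic boundary
    fitting and peak extraction; norm-referenced Z-scoring, composite
    scores and deficit subgrouping; mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction, ANCOVA, age-partialled correlations;
    and causal-steps mediation with the Sobel test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
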