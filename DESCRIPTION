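Package: cogmaturity
Title: Cognitive Maturity Index Estimation from Neurocognitive Task Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating an adolescent Cognitive Maturity Index (CMI)
    from longitudinal neurocognitive task data. Scores trial-level continuous
    performance (signal detection d-prime and log response bias), wheel-of-fortune
    gambling, emotional face recognition, and temporal delay discounting sessions
    into indicator variables; fits confirmatory factor and structural equation
    models by full-information maximum likelihood with missing data; predicts
    chronological age from latent factor scores with regularized regression under
    leave-one-participant-out cross-validation; and computes the CMI as the gap
    between predicted cognitive age and chronological age. Includes a synthetic
    longitudinal cohort generator with known ground truth for end-to-end
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
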