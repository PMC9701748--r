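Package: icpbin
Title: Invariant Causal Prediction for Rare Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Invariance-based causal prediction (ICP) for a binary outcome
    observed across two-level environments. For every candidate predictor
    subset the outcome is fit by logistic regression, response residuals are
    compared across environment levels with a Welch two-sample t-test, and
    the causal-parent estimate is the intersection of all subsets whose
    invariance is not rejected. Includes lasso pre-screening to keep the
    exhaustive subset search tractable, structural-causal-model simulators
    with per-environment interventions for validating the coverage
    guarantee, a rare-event cohort emulator for end-to-end pipeline runs,
    and simulation harnesses for coverage, parent recovery and
    indeterminacy under class imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    glmnet,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
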