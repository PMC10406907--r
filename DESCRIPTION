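Package: ridgeboost
Title: Interpretable Component-Wise Boosting with Ridge Base-Learners and
    Two-Step Interaction Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Component-wise gradient boosting for binary outcomes on grouped
    tabular (survey-style) data, built from ridge-penalized least-squares
    base-learners whose penalties are calibrated to a common effective degrees
    of freedom. Supports plain component-wise boosting, group and sparse-group
    boosting with a mixing parameter that balances individual against group
    selection, and a two-step (K-step) boosting procedure that fits main
    effects first and screens moderator-by-variable interactions second, which
    makes interaction detection feasible when the interaction design has more
    columns than observations. Includes 10-fold cross-validated early
    stopping, likelihood-reduction variable importance, aggregated effects and
    odds ratios, partial-effect and univariate interaction probability
    profiles, train/test splitting with rank-based AUC evaluation, and a
    synthetic survey-data generator with planted main and interaction effects
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
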