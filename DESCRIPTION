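Package: solboost
Title: Temperature-Monotone Gradient Boosting for Pharmaceutical Solubility
    in Organic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts mole-fraction solubility of pharmaceutical solutes in
    organic solvents as a function of temperature with regularized
    second-order gradient-boosted regression trees carrying a positive
    monotonic constraint on the temperature feature. Provides thermodynamic
    feature engineering (melting properties, a linear-in-temperature heat
    capacity difference, Hansen solubility parameter, solvent dielectric
    constant and boiling point), grouped and leave-one-solute-out validation,
    grid-search hyperparameter optimization with k-fold cross-validation,
    logarithmic error metrics (RMSLE in two conventions, MAPD, R squared),
    per-system evaluation reports, and a synthetic solubility-corpus
    generator built on heat-capacity-corrected ideal solubility with a
    descriptor-driven activity penalty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
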