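Package: healthineq
Title: Weighted Concentration Indices for Socio-Economic Inequalities in
    Health Between Schooling Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether a policy exposure (here, comprehensive
    versus selective secondary schooling) changed socio-economic inequalities
    in adult health.  Provides inverse-probability weighting of a binary
    school-system exposure on pre-secondary-school confounders (main-effects,
    spline-expanded and ridge-penalized logistic candidates plus exact-moment
    entropy balancing, selected by achieved covariate balance), weighted
    regression-based concentration indices of health inequality in absolute
    (Erreygers-type), relative-attainment and relative-shortfall form with a
    school-system interaction contrast, a two-stage missing-data strategy
    combining inverse-probability-of-response weights with chained-equation
    multiple imputation and Rubin pooling, and a synthetic two-cohort
    generator with planted, analytically known inequality for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    MASS,
    sandwich,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
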