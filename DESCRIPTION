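Package: cfmtools
Title: Coexisting Forms of Child Malnutrition: Classification, Survey
    Estimation and Determinant Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of coexisting forms of malnutrition (CFM)
    in children under five from survey microdata. Computes length/height-for-age,
    weight-for-age and weight-for-length/height z-scores with the LMS method
    against pluggable growth-reference tables, applies biological-plausibility
    exclusions, classifies each child into a nine-way mutually exclusive
    nutritional-status taxonomy (normal, the four standalone forms, and the
    composite types CUW, CUS, CUWS and CSO), produces survey-weighted prevalence
    estimates with confidence intervals at national, regional and global levels,
    and fits multinomial logistic regression models with chi-square screening,
    backward elimination and collinearity diagnostics. A synthetic microdata
    generator with known ground truth (correlated z-scores, planted covariate
    odds ratios, sampling weights, cluster and country structure) makes every
    pipeline stage testable without access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
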