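Package: matcov
Title: Estimating Coverage of Minimally Adequate Treatment for Major
    Depressive Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the proportion of people with major
    depressive disorder who receive minimally adequate treatment (MAT) by
    location, age, sex, and year from sparse survey data. Implements
    indicator crosswalking via a trimmed mixed-effects network
    meta-analysis on logit differences with a healthcare-access effect
    modifier, sex-splitting of both-sex estimates, a hierarchical
    location-cascade meta-regression with age-pattern constraints, and
    draw-based prevalence-weighted aggregation with percentile uncertainty
    intervals. A synthetic-data generator reproduces the statistical
    structure of the survey inputs so that every stage can be validated by
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
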