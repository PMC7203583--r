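Package: surfrax
Title: Surrogate FRAX-Style Fracture Probability Models and Hip Fracture
    Burden Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing surrogate country models of
    10-year fracture probability. Implements a two-decrement (fracture versus
    death) probability engine driven by age- and sex-specific hip fracture
    incidence and mortality tables with multiplicative clinical risk factor
    and bone mineral density adjustment, construction of surrogate models
    that pair one country's fracture hazards with another country's
    mortality, a clinical-scenario grid comparison protocol (piecewise linear
    regression with a fixed knot, percentile differences, nonparametric
    tolerance intervals), and demographic projection of national hip fracture
    counts under stable incidence. A synthetic-data module generates
    Gompertz-structured incidence, mortality, fracture-ratio and population
    tables with known parameters, plus a Monte Carlo cohort oracle for the
    probability engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
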