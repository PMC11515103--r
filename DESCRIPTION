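Package: shockbias
Title: Simulating Composite-Allocation Bias in the ATLS Hypovolemic Shock Classification
Version: 1.0.0
Authors@R: person("shockbias", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Monte-Carlo audit of the "highest shock class" composite allocation used when
    comparing base deficit against traditional vital parameters (heart rate, systolic blood
    pressure, Glasgow Coma Scale) in the ATLS classification of hypovolemic shock. Generates
    Gaussian-copula cohorts of synthetic multitrauma patients with Spearman-targeted dependence
    and physiologically truncated marginals, classifies each patient into shock classes I-IV per
    parameter, forms the maximum-over-members composite class, and quantifies how the composite
    allocation systematically biases per-class transfusion comparisons in favour of whichever
    parameter is left outside the composite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
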