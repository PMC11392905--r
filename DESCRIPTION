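Package: aquanit
Title: Water-Nitrogen Optimization for Drip-Fertigated Factorial Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-factor (irrigation x nitrogen) drip
    fertigation trials: leaf area index and dry-matter scaling, logistic
    growth-curve fitting with rapid-growth characteristic parameters,
    water-balance evapotranspiration and productivity indices (WUE, IWUE,
    NPFP), two-way ANOVA with Duncan's multiple range test, quadratic
    response-surface fitting in (water consumption, nitrogen rate) with
    box-constrained maximization, and multi-objective acceptability-region
    intersection yielding recommended water and nitrogen intervals. Includes
    a synthetic trial generator with exported ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
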