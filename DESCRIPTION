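Package: ssme
Title: Small-Scale Metabolism-and-Expression Models of the Rate-Yield Tradeoff
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based small-scale metabolism-and-expression (SSME)
    modeling of aerobic overflow metabolism in Escherichia coli. Builds a
    three-pathway proteome-allocation model in the ME-model formalism
    (fluxes coupled to enzyme amounts through effective turnover rates),
    solves yield-maximized growth phenotypes and feasible solution-space
    envelopes by linear programming with growth-rate bisection, perturbs the
    model (proton leak, alternative-pathway extensions, knockouts), calibrates
    global parameters (k_eff, unmodeled protein fraction, maintenance
    energies) to growth phenotype data, and analyzes rate/yield/acetate
    phenotype tables for the two-dimensional rate-yield tradeoff: the
    growth-rate versus yield tradeoff along yield-maximized solutions and the
    glucose-uptake versus yield tradeoff at fixed growth rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
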