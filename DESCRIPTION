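Package: emuflux
Title: Carbon-13 Metabolic Flux Analysis by Elementary Metabolite Unit Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of mass isotopomer distributions (MDVs) of metabolite
    fragments at isotopic steady state and isotopically nonstationary (INST)
    state by elementary metabolite unit (EMU) decomposition of atom-mapped
    metabolic networks, and estimation of intracellular fluxes and metabolite
    pool sizes from labeling measurements by multi-start weighted nonlinear
    least squares. Includes constraint-based pre-analysis (flux balance and
    flux variability analysis, hit-and-run sampling of the flux polytope),
    measurement processing (convolution, natural-abundance and inoculum
    corrections, tracer MDV construction), dilution (G-value) modeling, and a
    post-fit statistics layer (chi-square goodness of fit, residual normality,
    Hessian-based and Monte-Carlo confidence intervals, sensitivity and
    contribution matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    MASS,
    Matrix,
    minpack.lm,
    parallel,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
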