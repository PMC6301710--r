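Package: pdodfba
Title: Dynamic Flux Balance Analysis of 1,3-Propanediol Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dynamic flux balance analysis (DFBA) of glycerol fermentation to
    1,3-propanediol (PDO) by Clostridium butyricum. Provides a reduced
    stoichiometric model of anaerobic glycerol metabolism with a nonlinear
    growth-per-flux objective switched by extracellular glycerol, kinetic
    flux constraints (Ghose-Tyagi substrate-inhibited uptake, a logistic
    acetate secretion ceiling, regime-dependent death constants), three DFBA
    solution strategies (dynamic optimization by orthogonal collocation,
    static optimization, and direct integration), batch and fed-batch
    reactors, global sensitivity analysis (multi-parametric sensitivity
    analysis with Kolmogorov-Smirnov classification, and partial rank
    correlation coefficients), a Monte-Carlo population balance model of
    cell-to-cell variability, design-space scans of culture conditions, and
    generators plus fitting routines for pseudo-experimental fermentation
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
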