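Package: stemtaper
Title: Stem Taper Equations, Machine-Learning Regressors and Volume
    Estimation for Tropical Forest Inventories
Version: 0.1.0
Authors@R:
    person("Forest", "Biometrics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling stem taper (the decrease of outside-bark
    diameter with height along a tree bole) in structurally complex tropical
    forests.  Provides six literature taper equations (Demaerschalk, Biging,
    Bi, Lee, Kozak, Metcalf) fitted per forest type by Gauss-Newton nonlinear
    least squares with AICc model selection, accumulated stem volume by
    numerical integration of the fitted taper law, pooled multilayer
    perceptron (resilient backpropagation) and random-forest regressors for
    diameter and accumulated volume, Smalian-formula stem geometry for
    multi-stemmed trees via equivalent diameters, a repeated tree-level
    75/25 cross-validation harness reporting RMSE, bias and model
    efficiency, and a synthetic three-site inventory generator so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
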