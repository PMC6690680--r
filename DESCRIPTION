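Package: pecgsim
Title: Simulated Ischemic Pseudo-ECGs from Calibrated Populations of
    Human Ventricular Myocyte Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for the early detection of acute myocardial
    ischemia from the electrocardiogram. Implements the ten Tusscher-Panfilov
    2006 human ventricular myocyte model with an acute-ischemia overlay
    (ATP-sensitive potassium current, hyperkalemia, sodium and L-type calcium
    current inhibition), experimentally-calibrated populations of models built
    by Latin hypercube sampling of ionic conductances, 1D cable simulations
    with regional ischemia, pseudo-ECG synthesis at a virtual unipolar probe,
    automatic ECG biomarker delineation (QRS, QT, ST deviation, T wave), and
    from-scratch multilayer-perceptron classifiers that detect and grade
    ischemic severity from pseudo-ECG features, including Garson feature
    importance and a regularized logistic-regression baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
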