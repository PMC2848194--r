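Package: tanhnet
Title: Small Gene Regulatory Network Inference from Time-Course
    Expression via a Tanh Rate Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers small directed gene regulatory networks from
    time-course expression data (log-ratio scale) under a saturating
    tanh transcription-rate model. Network structure is searched by a
    genetic algorithm over per-gene in-degree encodings scored by AIC or
    BIC, optionally restricted to a power-law in-degree prior;
    parameters of each candidate regulator set are estimated by a
    stochastic-gradient-descent-enhanced simulated annealing optimizer
    with Metropolis-Hastings acceptance and multiplicative-perturbation
    restarts. Includes a benchmark simulator with SNR-controlled
    Gaussian noise and sinusoidal external factors, mean-filter
    smoothing, boxplot-outlier identification of external factors,
    confusion-based evaluation metrics (TPR, TNR, FPR, mFPR, mTPR*),
    and a scheme for merging two inferred subnetworks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
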