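Package: olfbayes
Title: Variational Bayesian Learning in an Olfactory Bulb Circuit Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rate-network simulator of unsupervised olfactory learning as
    online variational Bayesian inference. Mitral/tufted and granule cells
    jointly infer odor concentrations under a spike-and-slab prior while
    dendro-dendritic weights are learned with uncertainty-adaptive Hebbian
    plasticity. Includes the closed-form posterior transfer functions with a
    numerically stable Mills-ratio implementation and a quadrature oracle, a
    concentration-invariant piriform readout with lateral inhibition and
    top-down feedback, reward-prediction-error learning for a go/no-go task,
    a sparse-coding baseline learned by stochastic gradient ascent, and an
    evaluation suite (bootstrap selectivity, odor reconstruction, generalized
    ROC curves, normalized weight error, lifetime sparseness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
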