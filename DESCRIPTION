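Package: polargcn
Title: Graph-Convolutional Classification of Myocardial Perfusion Polar Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of myocardial-perfusion polar maps (normal versus
    abnormal, indicating coronary artery disease) with spectral graph
    convolutional neural networks, together with occlusion-based localization
    of pathological myocardial segments. Provides the 460-node polar-map
    geometry with AHA 17-segment and coronary-territory assignments, the
    unit-weight polar graph with its combinatorial Laplacian and a
    Graclus-style coarsening/pooling hierarchy, Chebyshev-polynomial and
    Cayley rational spectral filters, fully connected and 2-D convolutional
    baseline classifiers, seeded stochastic-gradient-descent training with
    stratified cross-validation and agreement/sensitivity/specificity/kappa
    reporting, and a synthetic polar-map cohort generator with segment-level
    ground truth so the entire pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
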