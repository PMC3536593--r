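Package: tlcnet
Title: Time-Lagged Correlation Inference of Biochemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs biochemical reaction networks from noisy concentration
    time series in two stages. The topology stage estimates time-lagged
    correlation tensors with a Voronoi-tessellation pair-density estimator,
    propagates measurement errors to an interspecies distance matrix, embeds it
    by Kruskal-Shepard multidimensional scaling (downhill simplex), and
    thresholds distances into an undirected interaction graph oriented by the
    lag of maximum correlation. The calibration stage fits generalized mass
    action rate constants by maximum likelihood on concentration increments
    (tridiagonal noise covariance) and prunes null-kinetics reactions whose
    relative standard error reaches a threshold. Includes a mass-action
    simulator of the gemcitabine metabolic pathway used as the validation
    benchmark, and sensitivity/accuracy scoring of inferred networks against a
    reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
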