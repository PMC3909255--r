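Package: lncProp
Title: Network Propagation for lncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coding-non-coding gene-disease bipartite association
    networks, weights their gene projection by the two-step resource
    allocation process, and scores every gene against a query disease with
    an iterative label-propagation algorithm. Includes leave-one-out
    cross-validation with rank-threshold ROC/AUC, degree-preserving
    bipartite randomization, multiple-survival-screening style robustness
    resampling, descriptive network topology statistics (degree
    distributions, clustering coefficients, giant components), and a
    synthetic bipartite network generator with planted disease-class
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
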