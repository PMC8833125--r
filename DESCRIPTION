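Package: metconn
Title: Group-Level Brain Metabolic Connectome Analysis for Small-Animal FDG-PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-level metabolic brain networks from regional
    FDG-PET standardized uptake values (SUV) by inter-subject Pearson
    correlation, binarizes them over a sparsity sweep, computes
    graph-theoretical global and nodal properties (characteristic path
    length, clustering, efficiencies, small-worldness against
    degree-preserving random ensembles, degree, betweenness centrality,
    nodal efficiency), compares groups with label-permutation tests on
    edges and on metric areas under the sparsity curve with
    false-discovery-rate control, and simulates network robustness under
    random node failure and betweenness-ordered targeted attack.
    Includes a synthetic-data generator with covariance block structure
    and plantable edge and hub differences so the entire pipeline is
    testable without scan data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
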