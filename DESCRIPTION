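Package: TADhier
Title: Hierarchical TAD Calling on Replicate Hi-C Contact Matrices by
    Sparse Online Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles hierarchical topologically associating domains (TADs)
    on Hi-C contact matrices, with or without replicates. Interaction
    frequencies in the lower triangle of normalized contact matrices are
    fitted by a multivariate linear regression over all-possible candidate
    TADs assembled from insulation boundaries; nonnegative sparse
    coefficients are obtained with an FTRL-Proximal online solver and
    significant disjoint, nested and partially overlapping TADs are
    reported via a right-tailed permutation test. Includes ICE and logCPM
    normalization, down-sampling, a negative-binomial contact-matrix
    simulator with layered ground-truth TAD hierarchies, and
    Jaccard/F1 reproducibility metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
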