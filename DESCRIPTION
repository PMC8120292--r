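Package: mrnet
Title: Causal Network Learning with Mendelian Randomization Constraints
    and Online FDR Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based learning of causal graphs from individual-level
    genomic data (genotypes and molecular phenotypes) or from a correlation
    matrix. Implements an order-independent PC-stable skeleton search whose
    per-test significance thresholds are set sequentially by the LOND rule,
    controlling the overall false discovery rate across the unknown number of
    independence tests; edge orientation under the principle of Mendelian
    randomization with corrected v-structure identification; a classic
    sepset-based CPDAG orientation mode for comparison; a linear-Gaussian
    structural-equation simulator with Hardy-Weinberg genotypes, mixture
    handling of undirected edges, outlier injection and discretization; robust
    correlation estimation for contaminated data; and graph-comparison metrics
    (direction-weighted recall and precision, adjusted structural Hamming
    distance, node-ordering stability, distance-based module clustering).
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
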