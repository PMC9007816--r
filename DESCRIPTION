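Package: lowmi
Title: Low-Precision Mutual Information Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fixed-point, lookup-table based estimation of mutual
    information with saturating frequency counters, and its use inside
    information-theoretic feature selection filters (MIM, mRMR, JMI) for
    high-dimensional gene-expression data. Includes equal-width
    discretization, ranking-similarity metrics (top-k true positive
    rate), a repeated stratified cross-validation harness with feature
    selection inside the loop, a deterministic microarray-like data
    generator with planted relevant, redundant and complementary
    features, CSV/ARFF readers and writers, and a command-line
    interface. Lets users measure how far the bit depth of the mutual
    information arithmetic can be lowered before feature rankings and
    downstream classification degrade.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    foreign,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
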