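Package: normbench
Title: Benchmarking Between-Sample Normalization Methods for RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes five between-sample scaling-factor normalizations for
    RNA-seq count matrices (trimmed mean of M-values, upper quartile,
    median-of-ratios, quantile, and PoissonSeq-style goodness-of-fit
    selection) from first principles, and benchmarks them on a two-group
    design by the bias and variance of analytically selected housekeeping
    genes, sensitivity and specificity against control gene lists,
    leave-one-out cross-validation classification error, common
    differentially-expressed-gene overlap, and rank clustering. Per-criterion
    ranks are aggregated into a final recommendation. A negative-binomial
    count simulator with known size factors, known differentially expressed
    genes and known housekeeping genes provides ground truth for every
    criterion, and a negative-binomial exact test consumes the scaling
    factors for differential expression calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    class,
    e1071,
    nnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
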