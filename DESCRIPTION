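Package: percnorm
Title: Percentile Normalization for Batch Effects in Case-Control
    Microbiome Studies
Version: 0.1.0
Authors@R:
    person("A.", "Rivera", email = "arivera@example.org",
           role = c("aut", "cre"))
Description: Model-free batch correction for case-control microbiome
    meta-analyses. Within each study, control feature distributions are
    converted to percentiles of themselves and case distributions to
    percentiles of the matched control distribution, after replacing zeros
    with tiny uniform pseudo relative abundances, so that normalized samples
    can be pooled across studies for non-parametric differential-abundance
    testing. Also provides the comparator corrections commonly benchmarked
    against it (empirical-Bayes location/scale batch adjustment and
    linear-model batch subtraction in log space), Wilcoxon rank-sum testing
    with Benjamini-Hochberg FDR control, Fisher and Stouffer p-value
    combination with an opposing-direction screen, Bray-Curtis distances
    with PERMANOVA, a lognormal synthetic-data generator with study-specific
    batch shifts, and in-silico control-titration and null false-positive
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    jsonlite
Config/testthat/edition: 3
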