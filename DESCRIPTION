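Package: condoverlap
Title: Conditional Overlap Analysis for Lists of Differential Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates, tests, and identifies the overlap between sets of
    differential features (peaks, genes) obtained from two or more
    differential analyses. Instead of intersecting thresholded hit lists,
    the features called significant in one experiment are used as a
    conditioning set, and the proportion of truly differential features
    among them in a second experiment is estimated from the conditional
    p-value distribution; a resampling null distribution over random
    feature sets of the same size provides the significance assessment.
    Includes Storey-type estimation of the proportion of true null
    hypotheses (pi0) with bootstrap, smoother, and fixed-lambda selection,
    q-value computation, chaining of the conditional analysis across three
    or more experiments with direction-concordance filtering,
    sliding-rank-threshold conditional-proportion scans over mapped
    feature pairs (for example promoter peaks to downstream genes),
    gene-set collective-shift tests against resampled same-size sets, and
    a ground-truth Monte-Carlo simulation study for validating
    false-discovery control of the identified overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
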