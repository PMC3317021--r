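Package: wgafidelity
Title: Fidelity Assessment of Whole-Genome Amplification by Array CGH
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how faithfully whole-genome amplification
    (WGA) preserves DNA copy-number signal in two-channel array-CGH
    experiments. Implements subgrid intensity normalization of spot
    quantification tables, log2-ratio profile construction with median
    centering and median-absolute-value scaling, circular binary
    segmentation with permutation testing, moving-average smoothing with
    signed peak detection, and three concordance statistics between
    amplified samples and their non-amplified controls (per-spot gain/loss
    agreement, genome-length agreement of same-sign segments, and matched
    signed peaks), benchmarked against duplicate control hybridizations
    with the exact two-tailed Mann-Whitney U test. Includes delta-delta-Ct
    quantification of Q-PCR validation assays and a synthetic two-channel
    array generator with configurable WGA artifact models (random sign
    flips, recurrent clone bias, regional amplification bias) so the whole
    pipeline can be exercised without microarray scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
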