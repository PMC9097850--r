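Package: rgstab
Title: Reference Gene Stability Analysis for RT-qPCR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Validation of candidate reference (housekeeping) genes for
    RT-qPCR normalization in a spatiotemporal brain-ischaemia design.
    Implements the four standard stability algorithms (comparative delta-Ct,
    geNorm M with iterative ranking and pairwise variation V, the NormFinder
    variance-decomposition model, and BestKeeper descriptive statistics with
    index correlation), RefFinder-style aggregation of per-method ranks by
    geometric mean, a per-region variance screen with fold-change reporting,
    and a seeded Ct-data simulator emulating a rat transient middle cerebral
    artery occlusion (tMCAO) study: SHAM/tMCAO conditions at four
    post-reperfusion time points in three brain regions, six candidate genes,
    n = 8 animals per group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
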