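Package: xomics
Title: Cross-Omics Differential Expression Integration and Random-Forest
    Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates a paired-design RNA-seq transcriptome with a
    time-course proteome. Provides per-pair exact-test differential
    expression with a cross-pair consensus rule, two-stage normalization
    and confidence-interval cutoff calling for time-course protein
    intensities, direction-consistent cross-omics intersection with exact
    hypergeometric overlap p-values, a modified two-tailed rank-rank
    hypergeometric overlap (RRHO) comparison with Benjamini-Yekutieli
    correction, prior-knowledge regulatory network assembly, and
    random-forest gene-regulatory-network inference with a permutation
    null and prior-conditioned edge selection. A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    pROC
Config/testthat/edition: 3
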