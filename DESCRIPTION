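Package: juryde
Title: Consensus Differential Expression and Trajectory Analysis for Staged Stress RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jury-based consensus calling of differentially expressed genes from
    staged (time-course) RNA-seq count matrices, built around three simplified
    negative-binomial/linear-model callers (an exact conditional NB test, an NB
    GLM Wald test, and a precision-weighted moderated-t caller), against-reference
    and time-course contrast schemes, union (J1) and intersection (J3) jury
    aggregation, 27-way expression-trajectory categorization, per-category
    Fisher-exact GO-term enrichment with DAG propagation, and mirror-image
    enzyme-code contingency comparisons. Includes a negative-binomial count
    simulator with designed trajectories and planted annotation enrichment so the
    whole pipeline is testable without external data, plus replicate-quality
    diagnostics (distance matrices, PCA, outlier flags).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma
Config/testthat/edition: 3
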