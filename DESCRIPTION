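Package: amylaudit
Title: Auditing Amyloid Hexapeptide Classifier Panels and Their Training Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for auditing fixed-length peptide training sets and panels of
    binary amyloid-propensity classifiers. Quantifies position-specific residue
    composition bias against a background amino-acid distribution (ratio tables
    and sequence-logo information content), measures exact-sequence leakage
    between datasets, clusters classifier decision vectors with binary
    similarity measures (Sokal-Michener, Rogers-Tanimoto, Sokal-Sneath) across
    a suite of hierarchical, divisive and k-medoids algorithms, selects the
    number of clusters by the Baker-Hubert Gamma index, validates cluster
    stability by resampled merged consensus clustering with membership
    robustness, and audits a focal classifier against the unanimous vote of the
    remaining panel. A synthetic-data module generates peptide sets with a
    planted motif bias and classification matrices with planted method blocks
    plus an outlier, so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    cluster,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
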