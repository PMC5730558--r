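Package: gliomaTME
Title: Immune Microenvironment Profiling of Experimental Rat Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for profiling the immune microenvironment of
    experimental rat C6 gliomas and comparing it with human glioblastoma.
    Provides quadrant-gate flow-cytometry population quantification with
    isotype-derived thresholds, Welch-t differential expression with a
    plug-in false discovery rate estimate, rank-based Gene Ontology term
    enrichment with Benjamini-Hochberg correction, M1/M2/GAM marker-panel
    reporting, and cross-species glioma-subtype similarity scoring via
    one-sample Kolmogorov-Smirnov signature assignment and Spearman
    correlation of ortholog-mapped fold changes. A seeded synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
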