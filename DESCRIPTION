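Package: exosig
Title: Exosome Proteomics Differential Signatures and Prognostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free exosome proteomics of
    carboplatin-resistant canine osteosarcoma: peptide-to-protein fold-change
    aggregation by geometric medians over cross-replicate ratio combinations,
    column-sum normalization with t-score feature ranking and
    reference-relative log2 heatmap matrices, detection-set (Venn) logic,
    ortholog-similarity filtering, hypergeometric odds-ratio gene-set
    enrichment, a decomposed linear prognosis score with leave-one-out
    validation, and phenotype assay mathematics (generation time, MTS
    viability normalization, four-parameter logistic IC50 fitting, and
    disease-free-interval cohort assignment). A synthetic-data module
    emulates every input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
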