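Package: prolncs
Title: Proliferative Subtypes and Prognostic lncRNA Signatures from Bulk
    Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering proliferation-driven
    tumor subtypes and prognostic long non-coding RNA (lncRNA) signatures
    from bulk expression cohorts. Provides single-sample gene-set activity
    scoring (ssGSEA-style rank walk with a GSVA-like variant), consensus
    k-means subtype discovery with PAC model selection and silhouette core
    filtering, nearest-template subtype transfer with permutation
    confidence, a purity-adjusted partial-correlation framework (ProLnc)
    that scores every lncRNA against each pathway via preranked enrichment
    and a final significance index, bootstrap-stable univariate-Cox
    biomarker selection with cross-cohort consensus, a LASSO-Cox risk
    signature, and survival evaluation (Harrell C, IPCW time-dependent
    AUC, paired bootstrap C-index comparison). A synthetic multi-cohort
    generator with planted subtypes, modulators and hazards supplies
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    glmnet,
    jsonlite,
    limma,
    stats,
    survival,
    utils
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
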