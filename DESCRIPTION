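Package: moaprofile
Title: Mechanism-of-Action Classification from Cell Metabolic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for untargeted LC-MS cell metabolic profiling of
    drug-treated tumor cells: two-block (reversed-phase and HILIC) peak
    table handling, feature alignment, missing-value filtering, cell-count
    normalization, log10 transformation and Pareto scaling, PCA-based
    quality control of pooled QC samples, multi-class OPLS-DA with a
    NIPALS PLS2 backbone (VIP scores, sevenfold cross-validated Q2,
    permutation testing and CV-ANOVA), differential-metabolite selection
    (VIP, one-way ANOVA with Bonferroni correction, fold change, ROC AUC,
    clustered fold-change heat maps), and projection-based classification
    of new compound sample sets into mechanism-of-action classes
    (antimetabolite, DNA-acting, microtubule-affecting, RNA-interfering),
    including a mixed-mechanism flag. A synthetic-data generator emulates
    the full study design so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pheatmap
Config/testthat/edition: 3
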