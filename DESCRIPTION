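Package: methDriveR
Title: Discovery of Methylation-Silenced Drivers of Drug Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative discovery of promoter-hypermethylated, transcriptionally
    silenced genes associated with primary drug resistance in EGFR-mutant lung
    adenocarcinoma. Imputes per-patient log2(IC50) from expression with a ridge
    model trained on a cell-line panel, screens expression and promoter
    methylation against the imputed response with Spearman and empirical-Bayes
    moderated statistics, intersects the two screens under a hypermethylated /
    silenced / resistant sign constraint, and ranks candidates by bootstrap-LASSO
    stability-selection frequency. Also provides deterministic calculators for
    the validation assays (MSP relative methylation, delta-delta-Ct, CCK-8
    viability, four-parameter logistic IC50) and a synthetic-cohort generator
    with planted drivers for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
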