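Package: amsomics
Title: Multi-Omics Biomarker Discovery and Prediction of Acute Mountain Sickness
Version: 0.1.0
Authors@R:
    person("AMS", "Omics Team", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for plasma proteomic and
    metabolomic biomarker discovery of acute mountain sickness (AMS)
    susceptibility. Implements sample- and feature-level quality control
    (within-sample outlier masking, missingness filters, Kolmogorov-Smirnov
    sample exclusion), predictive-mean-matching imputation and cyclic loess
    normalization; protein-metabolite co-expression module discovery by
    Spearman/Ward hierarchical clustering with a dynamic hybrid tree cut,
    module eigengenes and module-trait association; feature selection by
    mutual-information-ranked recursive feature elimination with radial-kernel
    SVM error estimation and a Bonferroni-corrected univariate logistic filter;
    and a radial-kernel SVM prediction model evaluated with ROC/AUC,
    calibration, exact kernel SHAP attributions and decision curve analysis.
    A synthetic-cohort generator with a ground-truth manifest makes every
    stage testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    limma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
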