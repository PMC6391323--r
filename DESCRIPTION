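Package: metastrat
Title: Benchmarking Data-Merging and Results-Integration Strategies for
    Multi-Experiment LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Metastrat", "Developers", email = "metastrat@example.org",
           role = c("aut", "cre"))
Description: Tools to compare analytical strategies for two-experiment
    (multi-batch) LC-MS metabolomics studies: analysing each experiment on
    its own (SiE), integrating per-experiment results (ReIn), or directly
    merging the peak tables by m/z before analysis (DiMe). Provides peak
    table I/O, a synthetic dual-experiment generator with planted
    differential metabolites and batch effects, KNN missing-value
    imputation, MSTUS normalization, m/z-tolerance feature matching and
    table merging, Student's t-test and PLS-DA/VIP marker selection,
    ppm-window metabolite annotation, SVM classification with
    SEN/SPE/ACC/MCC/AUC metrics, half-sampling robustness (overlap values
    and co-identification profiles), and enrichment-factor evaluation of
    marker lists against experimentally validated true markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
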