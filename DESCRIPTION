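Package: signoise
Title: Signal and Noise Correlations in Task fMRI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates signal correlations (task-tuning similarity) and
    state-specific noise correlations (block-to-block functional connectivity)
    from beta-series regression of parcellated task fMRI, and analyses how
    task-state changes in noise correlation relative to rest align with the
    underlying signal correlation structure. Provides beta-series GLM fitting
    with nuisance regression and FIR residualization, SC/NC/deltaNC estimation
    with group averaging, the elementwise signal-noise differential and its
    aligned/anti-aligned classification, signed modularity, segregation and
    thresholded-PCA gradient network metrics, clique identification on
    thresholded differential graphs, shuffle-controlled multitask decoding,
    a closed-form linear statistical network model of state-specific
    correlations, and a synthetic multi-subject data generator with known
    population signal and noise structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
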