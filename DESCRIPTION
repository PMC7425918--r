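Package: msfs
Title: Multi-Stage Feature Selection for Ultra-Wideband Breast Tumor Size Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements a four-stage feature selection pipeline (MSFS) for
    classifying breast tumor size from forward-scattered ultra-wideband
    microwave signals: a bank of ten data normalization methods with
    PCA-based backward elimination under an ANOVA significance rule, ten
    statistical/time/frequency-domain feature extractors, ANOVA F-value
    ranking for selecting normalization methods and features, SVD-based
    fusion of the top-ranked feature columns into hybrid datasets, and
    stratified k-fold evaluation with linear SVM, probabilistic neural
    network and Gaussian naive Bayes classifiers. Includes a seeded
    synthetic phantom-signal simulator emulating the acquisition protocol
    (size- and location-dependent tumor echoes, additive noise, baseline
    drift) so the full pipeline can be exercised and validated without
    measurement hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
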