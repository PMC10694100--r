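Package: pvnf
Title: Single-Beat Discrimination of Pulmonary-Vein Nearfield from Atrial
    Farfield Bipolar Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying bipolar voltage electrograms recorded on an
    octapolar circular mapping catheter during pulmonary vein isolation into
    pulmonary-vein nearfield and atrial farfield components from a single beat.
    Implements the acquisition-chain band-pass and mains-notch filtering, a
    baseline noise gate, six electrogram features (high- and low-band spectral
    power from a sliding zero-padded FFT, relative high-band power, neighbour
    power ratio, bipolar amplitude, and the proportion of samples with steep
    slew rate), classifier training (decision tree, LDA, linear SVM, KNN) with
    skewness-corrected feature normalization, greedy forward feature selection,
    patient-level holdout validation with cross-validation, and bootstrap ROC
    confidence intervals. A synthetic circular-mapping-catheter simulator
    generates labelled recordings with realistic spectral separation, spatial
    decay across bipoles, and cryoballoon freeze-cycle delay sequences so the
    whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    MASS,
    rpart,
    class,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
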