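Package: eegreduce
Title: Electrode Reduction for EEG Speech-Imagery Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for finding minimal electrode subsets in multi-channel EEG
    decoding experiments, built around speech-imagery brain-computer
    interfaces. Implements greedy wrapper backward elimination, CSP-rank
    (multiclass and one-vs-all), and ICA-score electrode reduction; discrete
    wavelet, time/frequency feature-vector and common-spatial-pattern feature
    extraction; gradient-boosted, random-forest, support-vector and neural
    classifiers under one deterministic contract; a Mamdani fuzzy inference
    system that picks accuracy-vs-electrode-count operating points;
    dataset-size-adjusted decoding-significance thresholds; electrode
    occurrence maps and elbow clustering of removed-electrode counts; and a
    seeded synthetic-EEG generator so the whole pipeline is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    signal,
    xgboost,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
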