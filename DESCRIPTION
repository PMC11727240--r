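Package: occlusignal
Title: Occlusal Force Signal Simulation, Conditioning and Malocclusion
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing multichannel intraoral piezoelectric bite
    force recordings: a class-conditioned synthetic signal generator for
    Angle-class malocclusions (An I/II/III), open bite and mandibular
    deviation and for adverse oral habits (centric occlusion, lip biting,
    thumb sucking, teeth grinding); signal conditioning by zero-phase
    low-pass filtering, Fourier baseline-drift removal and FastICA source
    separation; per-window six-feature extraction (extrema, peak-to-valley
    interval, zero crossings, inflection points, energy); principal
    component analysis and t-distributed stochastic neighbour embedding
    implemented from first principles; and a balanced seven-model
    classification benchmark with confusion matrices, one-vs-rest ROC/AUC,
    precision-recall summaries and per-tooth-site permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    class,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
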