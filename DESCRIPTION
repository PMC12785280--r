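Package: pcgclass
Title: Hybrid MFCC-Wavelet Classification of Phonocardiogram Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for binary heart-sound (phonocardiogram)
    classification from WAV recordings. Recordings are resampled to 4000 Hz,
    peak-normalized and standardized to 3-second segments by trimming or
    cardiac-cycle duplication. Hybrid feature tables combine per-frame
    Mel-frequency cepstral coefficient statistics with six statistical
    descriptors (mean, standard deviation, variance, energy, Shannon energy,
    Shannon entropy) of four-level Daubechies wavelet subbands. Feature
    selection (greedy forward selection and a Boruta-style shadow-feature
    procedure), leakage-free z-score standardization, grid-searched support
    vector machine, logistic regression, decision tree and random forest
    classifiers, and confusion-matrix/ROC evaluation complete the pipeline.
    A synthetic phonocardiogram generator (S1/S2 bursts, systolic murmurs,
    extrasystoles) allows every stage to be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    rpart,
    ranger,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
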