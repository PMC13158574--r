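Package: adspeech
Title: Speech-Based Digital Biomarkers for Alzheimer's Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting Alzheimer's disease from
    spontaneous speech. Extracts phonological features (articulatory place and
    manner ratios, vowel classes, syllable structure via maximal-onset
    syllabification of ARPABET pronunciations) from CHAT transcripts, and
    acoustic and prosodic features (F0, jitter, shimmer, harmonics-to-noise
    ratio, MFCC, RASTA-filtered auditory spectrum, pause timing) from WAV
    audio through a low-level-descriptor-by-functional grid. Provides a
    two-stage feature-selection protocol (minimum-redundancy maximum-relevance
    screening followed by ANOVA, chi-square, information-gain and ReliefF
    ranking with letter grading), a classifier zoo with voting and stacking
    ensembles, cross-corpus evaluation, permutation importance, and a
    synthetic paired audio-plus-transcript corpus generator with a
    ground-truth ledger so that every pipeline stage is testable without
    access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    randomForest,
    xgboost,
    nnet,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
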