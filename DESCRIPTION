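Package: bowaves
Title: Bag-of-Waves Dictionary Learning and Interpretable Classification of
    Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns class-conditional dictionaries of short EEG waveforms by
    shift-invariant k-means with cosine-similarity assignment, encodes long
    recordings as bag-of-waves occurrence-count vectors over the concatenated
    dictionaries, and classifies individuals with L2-regularized multinomial
    logistic regression on TFIDF-weighted features under a nested
    leave-one-individual-out protocol.  Fitted classifiers are interpreted
    through closed-form Shapley values, average class-signed Shapley values,
    Welch power spectra of the critical waveforms, and waveform occurrence
    rates.  Includes a synthetic-cohort generator that plants known rhythmic,
    transient and slow-wave events at class-dependent rates on 1/f noise, plus
    readers and writers for EDF and a plain-text array container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
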