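Package: ccssp
Title: Joint Channel-Specific FIR and Spatial Filtering for Single-Trial EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns hybrid spatial-spectral filters for two-class single-trial
    EEG decoding by applying common spatial patterns (CSP) to time-delay
    embedded data: each eigenvector of a regularized generalized eigenvalue
    problem on the augmented channel-by-delay space encodes one FIR filter per
    channel together with a spatial weighting. Includes epoch container I/O
    (HDF5 and CSV), Butterworth/windowed-sinc preprocessing recipes, delay
    embedding, covariance estimation, the regularized generalized
    eigendecomposition, log-variance feature extraction, class-weighted SVM
    evaluation with balanced accuracy, cross-validated hyperparameter
    selection, filter interpretability analyses (per-delay spatial filters,
    per-channel FIR frequency responses, relative power spectra, filtered
    event-related potentials), a ground-truth synthetic EEG generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    rhdf5,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
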