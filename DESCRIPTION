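Package: ilmd
Title: Incremental Landmark Maximum Variance Unfolding for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid feature extraction and evaluation for two-class
    motor-imagery electroencephalography (MI-EEG). Implements a 1-D
    dual-tree complex wavelet transform with a catalogue of first-level
    and Q-shift filter banks, event-related desynchronization and
    synchronization (ERD/ERS) band-energy features over an automatically
    selected time block, landmark maximum variance unfolding (L-MVU)
    trained through an interior-point semidefinite solver, a constant-time
    incremental out-of-sample embedding (IL-MVU), feature fusion, linear
    discriminant classification, stratified cross-validation, Cohen's
    kappa and pooled two-sample t-tests. Includes a synthetic MI-EEG
    generator with planted contralateral ERD and ipsilateral ERS so the
    full pipeline can be exercised and validated without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), MASS, vegan, withr
Config/testthat/edition: 3
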