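Package: eznetsi
Title: Epileptogenic-Zone Localization from Preictal Scalp EEG via Source
    Imaging, Directed Networks and a Bistable Seizure Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Noninvasive localization of candidate epileptogenic zones from
    preictal scalp EEG. Reconstructs cortical sources with the standardized
    minimum-norm inverse (sLORETA) on a spherical head model, builds directed
    frequency-band networks from multivariate autoregressive models via the
    directed transfer function, scores regions by in/out/total degree
    centrality integrated over a sparsity-threshold sweep, and by a seizure
    index defined as the inverse mean escape time of a noise-driven bistable
    node model coupled through the directed network. Includes a ground-truthed
    synthetic preictal EEG generator, Welch spectral and Hilbert envelope
    tools, and diagnostic-test evaluation (sensitivity, specificity, accuracy,
    likelihood ratios, diagnostic odds ratio) with Wilson score intervals
    against a resection/outcome reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
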