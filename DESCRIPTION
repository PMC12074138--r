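Package: ecgStream
Title: Online ECG Biometrics from Streaming Heartbeat Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identity recognition from single-lead ECG traces that
    arrive as a stream of labeled data chunks. Heartbeats are segmented
    around Pan-Tompkins R peaks and summarised as one-dimensional
    multi-resolution local-binary-pattern histograms. An online learner
    then fits, chunk by chunk, a latent representation space by alternating
    closed-form least-squares updates over bidirectional regressions,
    Hadamard-code class prototypes, and a per-individual memory of mean
    representations, so that past raw data never need to be revisited.
    Includes synthetic generators for pseudo-ECG records and labeled
    feature streams, matching by nearest-neighbour projection, and
    identification-accuracy / equal-error-rate metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hadamard.R'
    'preprocess.R'
    'wfdb.R'
    'features.R'
    'memory.R'
    'learner.R'
    'evaluate.R'
    'simulate.R'
    'io.R'
    'stream.R'
    'cli.R'
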