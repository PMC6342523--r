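Package: cnmfr
Title: Constrained Non-Negative Matrix Factorization for Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source extraction for fluorescence calcium imaging movies by
    constrained non-negative matrix factorization (CNMF). Provides batch
    patch-parallel extraction with memory-mapped movie access, a streaming
    (online) mode with per-frame trace updates and residual-buffer detection
    of new components, sparse non-negative AR(1) deconvolution of calcium
    traces, component quality assessment (spatial consistency, peak
    signal-to-noise ratio, footprint classification), baseline-normalized
    DF/F extraction, and registration of components across imaging sessions
    via Jaccard distances and optimal assignment. Includes a synthetic movie
    generator realizing the same generative model, so the full pipeline can
    be exercised and validated without external data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    pracma,
    clue,
    nnet,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
RoxygenNote: 7.3.3
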