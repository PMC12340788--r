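Package: erpsynth
Title: Conditioned Variational Autoencoder Synthesis of Event-Related
    Potentials from Concept Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic event-related potential (ERP) matrices from
    image or text concept embeddings with a cross-domain conditioned
    variational autoencoder (cVAE).  A convolutional cVAE compresses
    channel-by-time ERP trials into a Gaussian latent space conditioned on
    subject identity; a dense cross-domain network maps 512-dimensional
    multimodal concept embeddings into that latent space, so that decoding a
    mapped embedding yields a subject-specific synthetic ERP.  Includes the
    surrounding toolchain: EEG band filtering, epoching, statistical
    artifact control with spherical-spline channel interpolation, z-score
    normalization, a ground-truth synthetic ERP simulator with
    P100/N200/P300/LPP-like components and emotional-condition effects on
    the late positive potential, evaluation statistics (correlation maps,
    component scoring, V-pattern contrasts, latent-space decoding), and a
    MAT-compatible container format for datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
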