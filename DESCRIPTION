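Package: pafingerprint
Title: Photoacoustic Fingerprinting of Nanoparticles and Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of photoacoustic (PA) signals recorded
    by optofluidic microresonator sensors. Generates labelled synthetic PA
    traces as seeded sums of damped sinusoids with calibrated noise, computes
    one-sided FFT magnitude spectra with peak, signal-to-noise-ratio, onset
    delay and concentration-response estimators, matches unknown spectra
    against a fingerprint library of gold-nanoparticle geometries, and
    classifies red-blood-cell and whole-blood spectra with a one-dimensional
    convolutional feature extractor trained jointly with per-class prototype
    embeddings under a cross-entropy plus prototype-loss objective. Includes
    PCA and silhouette based evaluation of raw versus learned features and a
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
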