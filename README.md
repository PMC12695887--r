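# pafingerprint

Photoacoustic (PA) fingerprinting of nanoparticles and blood cells in R.

Optofluidic whispering-gallery-mode microresonators can pick up the faint
acoustic waves that particles and cells emit when a pulsed laser heats
them. The frequency content of those MHz-band acoustic transients — the
*PA fingerprint* — reflects the emitter's shape, composition and
morphology, so free-flowing gold nanoparticles can be identified by
spectral matching and red-blood-cell (RBC) species can be classified by
machine learning, even inside whole blood. No such dataset is public, so
this package ships a statistically faithful synthetic generator together
with the full analysis chain, making every stage testable end to end:

* **Synthesis** — labelled PA traces as seeded sums of damped sinusoids
  (`x(t) = Σᵢ Aᵢ e^{-(t-τ)/Tᵢ} sin(2πfᵢ(t-τ) + φᵢ) + ε(t)`), with
  per-measurement amplitude/frequency jitter, acoustic travel delay
  `τ = distance / sound speed`, and noise calibrated to a target SNR.
  Built-in template inventories: five RBC species (pig, sheep, turkey,
  goat, llama; dominant peak near 4 MHz, sheep at 3.9 MHz), five
  whole-blood species with three-fold measurement variability, and four
  gold-nanoparticle geometries (sphere, rod, cube, shell).
* **Signal processing** — one-sided FFT magnitude spectra, band-limited
  peak search, SNR and onset-delay estimation, saturating
  concentration-response fitting (slope 2.5 mV mL fM⁻¹ in the linear
  region), and cosine-similarity matching against a fingerprint library.
* **Learning** — a 1-D convolutional feature extractor `f(x, q)`
  (conv → ReLU → max-pool, twice, then a fully connected ReLU layer)
  trained jointly with one prototype embedding `m_y` per class under

  `loss = CE + λ·PL`,  `CE = −log p(y|x)`,
  `p(y|x) = e^{−‖f(x,q)−m_y‖} / Σₖ e^{−‖f(x,q)−m_k‖}`,
  `PL = ‖f(x,q)−m_y‖²`,  `λ = 0.1`, `K = 1` prototype per class.

  Prediction is nearest-prototype in Euclidean distance; data are split
  80/20 (stratified) before training.
* **Evaluation** — confusion matrices, PCA projections of raw spectra
  versus learned features, and mean silhouettes quantifying the
  raw-intermingled → learned-separated contrast.

## Worked example

```r
library(pafingerprint)

templates <- default_templates("rbc_species")
config    <- acquisition_config(seed = 7)     # 100 MHz, 50 us, 35 dB SNR

signal <- generate_signal(templates$sheep, config)
signal
#> <pa_signal> sheep: 5000 samples @ 100 MHz, peak |x| 1.14 mV

peak <- dominant_peak(compute_spectrum(signal))
peak$frequency / 1e6      # 3.94 -- the sheep fingerprint peak near 3.9 MHz
estimate_snr(signal)
#> <pa_snr> 35.16 dB (signal 3.44-4.44 MHz, noise 20.0-40.0 MHz)

dataset    <- generate_dataset(templates, 40, config)      # 200 traces
classifier <- train_classifier(dataset, train = train_config(seed = 1))
test_idx   <- classifier$split$index[classifier$split$set == "test"]
evaluate(classifier, pa_dataset(dataset$signals[test_idx],
                                class_names = dataset$class_names))
#> <pa_report> accuracy 1.000; silhouette raw 0.267 -> learned 0.941
```

The report reads: all 40 held-out spectra are assigned to the right
species, and while 2-D PCA of the raw spectra leaves the five species
intermingled (silhouette 0.27), the prototype-trained features form
well-separated clusters (silhouette 0.94).

Nanoparticle identification works by library matching:

```r
lib   <- build_fingerprint_library(default_templates("aunp_geometry"))
query <- compute_spectrum(generate_signal(
  default_templates("aunp_geometry")$nanorod,
  acquisition_config(noise_rms = 0.02, target_snr_db = NULL, seed = 5)))
match_spectrum(query, lib)$ranking
#>        label similarity
#> 1    nanorod  0.9863775
#> 2 nanosphere  0.2976709
#> 3   nanocube  0.1963710
#> 4  nanoshell  0.1386392
```

A command-line interface over the same pipeline
(`simulate`, `spectrum`, `snr`, `delay`, `concfit`, `match`, `train`,
`classify`, `evaluate`) is installed at `inst/cli/pa-fingerprint.R`;
see `?pa_cli`.

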