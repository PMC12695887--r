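# Shared fixtures: everything is generated in code, nothing on disk.

# Small, fast digitizer: 12.5 MHz over 10.24 us -> 128 samples.
small_config <- function(...) {
  acquisition_config(sampling_rate = 12.5e6, duration = 10.24e-6,
                     noise_rms = 0, target_snr_db = NULL, ...)
}

# One-component template, optionally jitter-free.
tone_template <- function(name = "tone", f = 4e6, amp = 1, damp = 5e-6,
                          phase = 0, aj = 0, fj = 0) {
  species_template(name, list(spectral_component(f, amp, damp, phase)),
                   amplitude_jitter = aj, frequency_jitter = fj)
}

# Bare pa_signal from a sample vector (bypasses the generator).
raw_signal <- function(samples, fs = 100e6, label = NULL) {
  structure(list(samples = samples, sampling_rate = fs, trigger_time = 0,
                 label = label, provenance = list()),
            class = "pa_signal")
}

# Bare pa_spectrum on an explicit grid.
raw_spectrum <- function(frequencies, magnitudes, normalization = "raw") {
  structure(list(frequencies = frequencies, magnitudes = magnitudes,
                 normalization = normalization, window = "none",
                 n_samples = NA_integer_, sum_squares = NA_real_,
                 source = NA_character_, label = NULL),
            class = "pa_spectrum")
}

# Two-class dataset whose spectra are trivially separable (distant
# dominant peaks), for convergence tests.
separated_dataset <- function(n_per_class = 10, seed = 1) {
  tpls <- list(tone_template("low", f = 3e6, aj = 0.02, fj = 0.001),
               tone_template("high", f = 7e6, aj = 0.02, fj = 0.001))
  cfg <- acquisition_config(noise_rms = 0.01, target_snr_db = NULL,
                            seed = seed)
  generate_dataset(tpls, n_per_class, cfg)
}

# Small extractor for fast training tests.
tiny_model_config <- function(seed = 1) {
  model_config(input_length = 128L, conv_kernels = list(c(7L, 8L), c(5L, 8L)),
               pool_width = 4L, feature_dim = 16L, seed = seed)
}
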