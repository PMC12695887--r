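#' Acquisition configuration for synthetic photoacoustic traces
#'
#' Describes the digitizer and the measurement geometry used to render a
#' template into a time-domain trace. Defaults are 100 MHz sampling over
#' 50 microsecond records: Nyquist (50 MHz) sits far above the few-MHz
#' photoacoustic band and the 5000-sample records keep desk-scale studies
#' fast. When `target_snr_db` is set the generator calibrates the additive
#' white Gaussian noise level so that [estimate_snr()] with its default
#' bands reports that value; otherwise `noise_rms` is used directly.
#'
#' @param sampling_rate Digitizer rate in Hz.
#' @param duration Record length in seconds; `sampling_rate * duration`
#'   must be a whole number of samples, at least 64.
#' @param noise_rms Additive noise RMS in mV (ignored when `target_snr_db`
#'   is non-`NULL` and the rendered signal is non-zero).
#' @param target_snr_db Optional target SNR in dB for noise calibration.
#' @param distance Particle-to-resonator distance in metres (>= 0); the
#'   acoustic travel time `distance / sound_speed` delays the trace onset.
#' @param sound_speed Speed of sound in the medium, m/s (default: water).
#' @param pulse_repetition Laser pulse repetition rate in Hz (metadata).
#' @param seed Integer seed for every random draw tied to this config.
#'
#' @return An object of class `pa_config`.
#' @export
acquisition_config <- function(sampling_rate = 100e6, duration = 50e-6,
                               noise_rms = 0.02, target_snr_db = 35,
                               distance = 0, sound_speed = 1480,
                               pulse_repetition = 60, seed = 1L) {
  n <- sampling_rate * duration
  if (!is_scalar_num(sampling_rate) || sampling_rate <= 0)
    stop_pa("sampling_rate must be positive (Hz)")
  if (!is_scalar_num(duration) || duration <= 0)
    stop_pa("duration must be positive (s)")
  if (abs(n - round(n)) > 1e-6 || round(n) < 64)
    stop_pa("sampling_rate * duration must be an integer sample count >= 64")
  if (!is_scalar_num(noise_rms) || noise_rms < 0)
    stop_pa("noise_rms must be >= 0 (mV)")
  if (!is.null(target_snr_db) && !is_scalar_num(target_snr_db))
    stop_pa("target_snr_db must be NULL or a finite number (dB)")
  if (!is_scalar_num(distance) || distance < 0)
    stop_pa("distance must be >= 0 (m)")
  if (!is_scalar_num(sound_speed) || sound_speed <= 0)
    stop_pa("sound_speed must be positive (m/s)")
  if (!is_scalar_num(pulse_repetition) || pulse_repetition <= 0)
    stop_pa("pulse_repetition must be positive (Hz)")
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         n_samples = as.integer(round(n)), noise_rms = noise_rms,
         target_snr_db = target_snr_db, distance = distance,
         sound_speed = sound_speed, pulse_repetition = pulse_repetition,
         seed = as.integer(seed)),
    class = "pa_config"
  )
}

# Default SNR measurement bands shared by the generator's noise
# calibration and estimate_snr(): signal band = dominant peak +/- 0.5 MHz,
# noise band 20-40 MHz (clipped to Nyquist; for low-rate configs whose
# Nyquist is below 25 MHz, the upper 40-80 % of the grid is used instead).
snr_default_bands <- function(f_dominant, nyquist) {
  sig <- c(max(0, f_dominant - 0.5e6), min(nyquist, f_dominant + 0.5e6))
  if (nyquist > 25e6) {
    noi <- c(20e6, min(40e6, 0.98 * nyquist))
  } else {
    noi <- c(0.4, 0.8) * nyquist
  }
  if (noi[1] < sig[2]) noi[1] <- min(sig[2] * 1.2, 0.9 * noi[2])
  list(signal = sig, noise = noi)
}

# One-sided band power of a real vector: sum of |X_k|^2 over FFT bins whose
# frequency lies in [band[1], band[2]]. No interior-bin doubling; the
# convention cancels wherever band powers are compared.
band_power <- function(x, sampling_rate, band) {
  n <- length(x)
  xk <- stats::fft(x)[seq_len(n %/% 2 + 1L)]
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * sampling_rate / n
  idx <- which(freqs >= band[1] & freqs <= band[2])
  sum(Mod(xk[idx])^2)
}

#' Render one synthetic photoacoustic trace
#'
#' Draws per-measurement amplitude and frequency jitters from the seeded
#' stream, then renders the template as a sum of damped sinusoids delayed
#' by the acoustic travel time `tau = distance / sound_speed`, plus
#' additive white Gaussian noise:
#' `x(t) = sum_i A_i exp(-(t - tau)/T_i) sin(2 pi f_i (t - tau) + phi_i) [t >= tau] + e(t)`.
#' The output is fully deterministic given `(template, config, seed)`.
#'
#' @param template A [species_template()].
#' @param config An [acquisition_config()].
#' @param seed Seed for this trace; defaults to `config$seed`.
#'
#' @return A `pa_signal`: list with `samples` (mV), `sampling_rate`,
#'   `trigger_time` (0 by convention), `label` and `provenance`.
#' @export
#' @examples
#' sig <- generate_signal(default_templates("rbc_species")$sheep,
#'                        acquisition_config(seed = 7))
#' dominant_peak(compute_spectrum(sig))
generate_signal <- function(template, config, seed = NULL) {
  stopifnot(inherits(template, "pa_template"), inherits(config, "pa_config"))
  seed <- as.integer(seed %||% config$seed)
  nyq <- config$sampling_rate / 2
  f0 <- vapply(template$components, `[[`, numeric(1), "frequency")
  if (any(f0 >= nyq))
    stop_pa("component frequency %.3g Hz is at or above Nyquist (%.3g Hz)",
            max(f0), nyq)

  n <- config$n_samples
  t <- (seq_len(n) - 1L) / config$sampling_rate
  tau <- config$distance / config$sound_speed
  a0 <- vapply(template$components, `[[`, numeric(1), "amplitude")
  tc <- vapply(template$components, `[[`, numeric(1), "damping_time")
  ph <- vapply(template$components, `[[`, numeric(1), "phase")

  samples <- withr::with_seed(seed, {
    k <- length(f0)
    vs <- template$variability_scale
    f <- f0 * (1 + stats::rnorm(k) * template$frequency_jitter * vs)
    a <- pmax(0, a0 * (1 + stats::rnorm(k) * template$amplitude_jitter * vs))
    if (any(f >= nyq))
      stop_pa("jittered component frequency exceeds Nyquist; reduce jitter")
    clean <- numeric(n)
    live <- t >= tau
    ts <- t[live] - tau
    for (i in seq_len(k)) {
      clean[live] <- clean[live] +
        a[i] * exp(-ts / tc[i]) * sin(2 * pi * f[i] * ts + ph[i])
    }
    sigma <- config$noise_rms
    if (!is.null(config$target_snr_db) && any(clean != 0)) {
      # Calibrate sigma so estimate_snr() recovers the target in
      # expectation. The estimator reports
      #   (2 (Ps + ms n s2) / n^2) / (s2 + Pn_clean / (M n)) = 10^(T/10)
      # where Ps / Pn_clean are the clean signal's band powers (the
      # signal's own spectral tail leaks into the noise band) and each
      # noise FFT bin contributes n * s2 of band power. Solve for s2.
      fdom <- f[which.max(a)]
      bands <- snr_default_bands(fdom, nyq)
      ps <- band_power(clean, config$sampling_rate, bands$signal)
      pn_clean <- band_power(clean, config$sampling_rate, bands$noise)
      freqs <- (seq_len(n %/% 2 + 1L) - 1L) * config$sampling_rate / n
      m_noi <- sum(freqs >= bands$noise[1] & freqs <= bands$noise[2])
      m_sig <- sum(freqs >= bands$signal[1] & freqs <= bands$signal[2])
      r <- 10^(config$target_snr_db / 10)
      s2 <- (2 * ps / n^2 - r * pn_clean / (m_noi * n)) /
        (r - 2 * m_sig / n)
      if (!is.finite(s2) || s2 <= 0)
        stop_pa(paste0("target_snr_db = %.1f dB is unreachable: the ",
                       "signal's own out-of-band content floors the SNR"),
                config$target_snr_db)
      sigma <- sqrt(s2)
    }
    if (sigma > 0) clean + stats::rnorm(n, 0, sigma) else clean
  })

  structure(
    list(samples = samples, sampling_rate = config$sampling_rate,
         trigger_time = 0, label = template$name,
         provenance = list(template = template$name, seed = seed,
                           config_digest = pa_digest(unclass(config)))),
    class = "pa_signal"
  )
}

#' @export
print.pa_signal <- function(x, ...) {
  cat(sprintf("<pa_signal> %s: %d samples @ %.3g MHz%s\n",
              x$label %||% "(unlabelled)", length(x$samples),
              x$sampling_rate / 1e6,
              sprintf(", peak |x| %.3g mV", max(abs(x$samples)))))
  invisible(x)
}

#' Generate a balanced labelled dataset
#'
#' Renders `n_per_class` traces per template. Per-trace seeds are derived
#' deterministically from `config$seed` and the (class, replicate) index,
#' so any subset of the dataset is reproducible independently of
#' generation order.
#'
#' @param templates Named or unnamed list of [species_template()]s with
#'   unique names.
#' @param n_per_class Number of traces per class (>= 1).
#' @param config An [acquisition_config()].
#'
#' @return A `pa_dataset`: list with `signals`, `class_names`, `counts`.
#' @export
generate_dataset <- function(templates, n_per_class, config) {
  stopifnot(is.list(templates), length(templates) >= 1L,
            inherits(config, "pa_config"))
  if (!is_scalar_num(n_per_class) || n_per_class < 1)
    stop_pa("n_per_class must be >= 1")
  nms <- vapply(templates, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_pa("duplicate template names: %s",
                                  paste(unique(nms[duplicated(nms)]),
                                        collapse = ", "))
  n_per_class <- as.integer(n_per_class)
  signals <- vector("list", length(templates) * n_per_class)
  k <- 0L
  for (ci in seq_along(templates)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      signals[[k]] <- generate_signal(
        templates[[ci]], config, seed = pa_child_seed(config$seed, ci, j))
    }
  }
  pa_dataset(signals, class_names = nms)
}

#' Construct a labelled signal set
#'
#' @param signals List of `pa_signal` objects, each carrying a label in
#'   `class_names`.
#' @param class_names Ordered class labels (>= 2 for classification use;
#'   defaults to the sorted unique labels present).
#' @param allow_empty Permit an empty signal list (requires explicit
#'   `class_names`); used for degenerate split results.
#' @return A `pa_dataset`.
#' @export
pa_dataset <- function(signals, class_names = NULL, allow_empty = FALSE) {
  stopifnot(is.list(signals))
  if (length(signals) == 0L && !(allow_empty && !is.null(class_names)))
    stop_pa("a dataset needs at least one signal")
  labs <- vapply(signals, function(s) s$label %||% NA_character_,
                 character(1))
  if (anyNA(labs)) stop_pa("every signal in a dataset must be labelled")
  class_names <- class_names %||% sort(unique(labs))
  if (!all(labs %in% class_names))
    stop_pa("signal labels outside class_names: %s",
            paste(setdiff(labs, class_names), collapse = ", "))
  structure(
    list(signals = signals, class_names = class_names,
         counts = table(factor(labs, levels = class_names))),
    class = "pa_dataset"
  )
}

#' @export
print.pa_dataset <- function(x, ...) {
  cat(sprintf("<pa_dataset> %d signals, %d classes\n",
              length(x$signals), length(x$class_names)))
  print(x$counts)
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset$signals, `[[`, character(1), "label")
}

#' Concentration-response configuration and series
#'
#' The photoacoustic amplitude grows linearly with analyte concentration
#' until it saturates:
#' `amplitude = min(intercept + slope * c, saturation_level) + noise`.
#' Defaults reproduce the package's reference response: slope
#' 2.5 mV mL fM^-1, zero intercept, a ten-point series over 2--20 fM, a
#' saturation ceiling above the series range, and noise at 2 % of the
#' maximal clean amplitude.
#'
#' @param slope Linear-region slope in mV mL fM^-1.
#' @param intercept Amplitude at zero concentration, mV.
#' @param saturation_level Amplitude ceiling, mV (> intercept).
#' @param concentrations Strictly increasing, non-negative fM values.
#' @param noise_rms Additive amplitude noise RMS, mV.
#' @param seed Integer seed.
#'
#' @return `concentration_response_config()` returns a `pa_crc`;
#'   `generate_concentration_series()` returns a data.frame with columns
#'   `concentration_fM` and `amplitude_mV`.
#' @export
concentration_response_config <- function(slope = 2.5, intercept = 0,
                                          saturation_level = 100,
                                          concentrations = seq(2, 20, by = 2),
                                          noise_rms = 1, seed = 1L) {
  if (!is_scalar_num(slope)) stop_pa("slope must be a finite number")
  if (!is_scalar_num(intercept)) stop_pa("intercept must be a finite number")
  if (!is_scalar_num(saturation_level) || saturation_level <= intercept)
    stop_pa("saturation_level must exceed the intercept")
  if (length(concentrations) < 1L)
    stop_pa("concentrations must be a non-empty numeric vector")
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stop_pa("concentrations must be non-negative and strictly increasing")
  if (!is_scalar_num(noise_rms) || noise_rms < 0)
    stop_pa("noise_rms must be >= 0")
  structure(
    list(slope = slope, intercept = intercept,
         saturation_level = saturation_level,
         concentrations = as.numeric(concentrations),
         noise_rms = noise_rms, seed = as.integer(seed)),
    class = "pa_crc"
  )
}

#' @rdname concentration_response_config
#' @param crc A `pa_crc` configuration.
#' @export
generate_concentration_series <- function(crc = concentration_response_config()) {
  stopifnot(inherits(crc, "pa_crc"))
  clean <- pmin(crc$intercept + crc$slope * crc$concentrations,
                crc$saturation_level)
  amp <- withr::with_seed(crc$seed, {
    clean + if (crc$noise_rms > 0)
      stats::rnorm(length(clean), 0, crc$noise_rms) else 0
  })
  data.frame(concentration_fM = crc$concentrations, amplitude_mV = amp)
}
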