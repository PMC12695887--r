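#' One-sided FFT magnitude spectrum
#'
#' Computes the one-sided magnitude spectrum of a uniformly sampled trace.
#' Convention: with `X = fft(x)` of length `n`, magnitudes are
#' `|X_k|, k = 0..floor(n/2)` on the frequency grid `k * fs / n`. Under
#' this convention Parseval's identity reads
#' `sum_k w_k |X_k|^2 = n * sum x^2`, with weight `w_k = 2` for interior
#' bins and `w_k = 1` at DC and (even `n`) Nyquist; see
#' [spectrum_energy()]. Records are gated transients so no window is
#' applied by default; a Hann window is available behind `window`.
#'
#' @param signal A `pa_signal` (>= 64 samples, all finite).
#' @param normalization `"raw"` keeps the magnitudes as defined above;
#'   `"unit-energy"` rescales them to unit Euclidean norm (used for
#'   library matching).
#' @param window `"none"` (default) or `"hann"`.
#'
#' @return A `pa_spectrum`: list with `frequencies` (Hz, from 0 to
#'   Nyquist), `magnitudes`, `normalization`, `n_samples`,
#'   `sum_squares` (of the analysed samples) and `source` digest.
#' @export
compute_spectrum <- function(signal, normalization = c("raw", "unit-energy"),
                             window = c("none", "hann")) {
  stopifnot(inherits(signal, "pa_signal"))
  normalization <- match.arg(normalization)
  window <- match.arg(window)
  x <- signal$samples
  n <- length(x)
  if (n < 64L) stop_pa("spectrum needs >= 64 samples, got %d", n)
  if (!all(is.finite(x))) stop_pa("signal contains non-finite samples")
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n))
  half <- n %/% 2 + 1L
  mag <- Mod(stats::fft(x))[seq_len(half)]
  freqs <- (seq_len(half) - 1L) * signal$sampling_rate / n
  if (normalization == "unit-energy") {
    nrm <- sqrt(sum(mag^2))
    if (nrm > 0) mag <- mag / nrm
  }
  structure(
    list(frequencies = freqs, magnitudes = mag,
         normalization = normalization, window = window,
         n_samples = n, sum_squares = sum(x^2),
         source = signal$provenance$config_digest %||% NA_character_,
         label = signal$label),
    class = "pa_spectrum"
  )
}

#' @export
print.pa_spectrum <- function(x, ...) {
  cat(sprintf("<pa_spectrum> %d bins, 0-%.3g MHz, %s normalization\n",
              length(x$magnitudes), max(x$frequencies) / 1e6,
              x$normalization))
  invisible(x)
}

#' Parseval energy check helper
#'
#' Returns the weighted spectral energy `sum_k w_k |X_k|^2 / n` for a raw
#' spectrum, which equals `sum x^2` of the analysed samples exactly (to
#' floating point) under the package FFT convention.
#'
#' @param spectrum A raw-normalization `pa_spectrum`.
#' @return Scalar spectral energy (mV^2 units times samples).
#' @export
spectrum_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "pa_spectrum"))
  if (spectrum$normalization != "raw")
    stop_pa("spectrum_energy() requires raw normalization")
  n <- spectrum$n_samples
  w <- rep(2, length(spectrum$magnitudes))
  w[1] <- 1
  if (n %% 2L == 0L) w[length(w)] <- 1
  sum(w * spectrum$magnitudes^2) / n
}

#' Dominant spectral peak in a band
#'
#' Frequency and magnitude of the maximum-magnitude bin inside `band`;
#' ties resolve toward the lower frequency.
#'
#' @param spectrum A `pa_spectrum`.
#' @param band Two-element band `(low, high)` in Hz containing >= 3 bins.
#'   Default 1--10 MHz, the band containing the photoacoustic peaks of
#'   interest.
#'
#' @return List with `frequency` (Hz) and `magnitude`.
#' @export
dominant_peak <- function(spectrum, band = c(1e6, 10e6)) {
  stopifnot(inherits(spectrum, "pa_spectrum"))
  if (length(band) != 2L || band[1] >= band[2])
    stop_pa("band must be (low, high) with low < high")
  idx <- which(spectrum$frequencies >= band[1] &
                 spectrum$frequencies <= band[2])
  if (length(idx) < 3L)
    stop_pa("band [%.3g, %.3g] Hz covers %d bins; need >= 3",
            band[1], band[2], length(idx))
  best <- idx[which.max(spectrum$magnitudes[idx])]
  list(frequency = spectrum$frequencies[best],
       magnitude = spectrum$magnitudes[best])
}

#' Resample a spectrum onto a new uniform grid
#'
#' Linear interpolation of the magnitudes onto `n_bins` uniform points
#' spanning `band`; out-of-range queries read as zero.
#'
#' @param spectrum A `pa_spectrum`.
#' @param n_bins Number of output bins.
#' @param band Frequency span in Hz; defaults to the spectrum's own span.
#' @return A `pa_spectrum` on the new grid (normalization preserved tag
#'   only; magnitudes are interpolated values, re-normalize as needed).
#' @export
resample_spectrum <- function(spectrum, n_bins, band = NULL) {
  stopifnot(inherits(spectrum, "pa_spectrum"), n_bins >= 2)
  band <- band %||% range(spectrum$frequencies)
  grid <- seq(band[1], band[2], length.out = n_bins)
  mag <- stats::approx(spectrum$frequencies, spectrum$magnitudes,
                       xout = grid, rule = 1)$y
  mag[is.na(mag)] <- 0
  out <- spectrum
  out$frequencies <- grid
  out$magnitudes <- mag
  out$n_samples <- NA_integer_
  out$sum_squares <- NA_real_
  out
}

#' Fingerprint library of reference spectra
#'
#' A labelled collection of reference spectra sharing one frequency grid,
#' used to identify unknown particles: the entry with the highest cosine
#' similarity to a query is the most likely match.
#'
#' @param entries Named list of `pa_spectrum` objects (unique labels,
#'   identical grids).
#' @return A `pa_library`.
#' @export
fingerprint_library <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  labs <- names(entries)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs))
    stop_pa("library entries must carry unique non-empty labels")
  for (e in entries) stopifnot(inherits(e, "pa_spectrum"))
  grid <- entries[[1]]$frequencies
  same <- vapply(entries, function(e)
    length(e$frequencies) == length(grid) &&
      max(abs(e$frequencies - grid)) < 1e-6, logical(1))
  if (!all(same)) stop_pa("all library spectra must share one frequency grid")
  structure(list(labels = labs, entries = entries,
                 frequencies = grid, similarity_metric = "cosine"),
            class = "pa_library")
}

#' Build a fingerprint library from templates
#'
#' Renders each template noiselessly under `config`, computes unit-energy
#' spectra and assembles them into a [fingerprint_library()].
#'
#' @param templates Named list of [species_template()]s.
#' @param config An [acquisition_config()]; its noise settings are
#'   overridden to zero for the reference renderings, and jitter is
#'   suppressed by rendering at the template's nominal parameters.
#' @param n_bins Optional resampling of the references to a coarser grid.
#' @export
build_fingerprint_library <- function(templates,
                                      config = acquisition_config(),
                                      n_bins = NULL) {
  ref_cfg <- acquisition_config(
    sampling_rate = config$sampling_rate, duration = config$duration,
    noise_rms = 0, target_snr_db = NULL, distance = config$distance,
    sound_speed = config$sound_speed,
    pulse_repetition = config$pulse_repetition, seed = config$seed)
  entries <- lapply(templates, function(tp) {
    tp0 <- tp
    tp0$amplitude_jitter <- 0
    tp0$frequency_jitter <- 0
    sp <- compute_spectrum(generate_signal(tp0, ref_cfg),
                           normalization = "unit-energy")
    if (!is.null(n_bins)) sp <- resample_spectrum(sp, n_bins)
    sp
  })
  names(entries) <- vapply(templates, `[[`, character(1), "name")
  fingerprint_library(entries)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match an unknown spectrum against a fingerprint library
#'
#' The query is interpolated onto the library grid, both sides are
#' unit-energy normalized, and cosine similarity is computed against every
#' reference. The highest-scoring reference is the most likely match;
#' ties resolve by library order.
#'
#' @param query A `pa_spectrum`.
#' @param library A `pa_library`.
#' @return List with `label`, `similarity` and `ranking` (a data.frame of
#'   all entries sorted by decreasing similarity).
#' @export
match_spectrum <- function(query, library) {
  stopifnot(inherits(query, "pa_spectrum"), inherits(library, "pa_library"))
  grid <- library$frequencies
  qr <- range(query$frequencies)
  if (qr[1] > max(grid) || qr[2] < min(grid))
    stop_pa("query grid [%.3g, %.3g] Hz does not overlap the library grid",
            qr[1], qr[2])
  q <- stats::approx(query$frequencies, query$magnitudes, xout = grid,
                     rule = 1)$y
  q[is.na(q)] <- 0
  sims <- vapply(library$entries, function(e)
    cosine_similarity(q, e$magnitudes), numeric(1))
  ord <- order(-sims) # stable: ties keep library order
  ranking <- data.frame(label = library$labels[ord],
                        similarity = unname(sims[ord]),
                        stringsAsFactors = FALSE)
  list(label = ranking$label[1], similarity = ranking$similarity[1],
       ranking = ranking)
}

#' Read and write spectra as delimited text
#'
#' Two-column tab-separated files with a header line
#' (`frequency_hz`, `magnitude`).
#'
#' @param spectrum A `pa_spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "pa_spectrum"))
  df <- data.frame(frequency_hz = sprintf("%.10e", spectrum$frequencies),
                   magnitude = sprintf("%.10e", spectrum$magnitudes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("frequency_hz", "magnitude") %in% names(df)))
    stop_pa("%s: expected columns frequency_hz, magnitude", path)
  fr <- suppressWarnings(as.numeric(df$frequency_hz))
  mg <- suppressWarnings(as.numeric(df$magnitude))
  bad <- which(!(is.finite(fr) & is.finite(mg)))
  if (length(bad))
    stop_pa("%s: non-numeric value near line %d", path, bad[1] + 1L)
  structure(
    list(frequencies = fr, magnitudes = mg,
         normalization = "raw", window = "none",
         n_samples = NA_integer_, sum_squares = NA_real_,
         source = NA_character_, label = NULL),
    class = "pa_spectrum"
  )
}

#' Serialize a fingerprint library to and from JSON
#'
#' @param library A `pa_library`.
#' @param path JSON file path.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "pa_library"))
  rec <- list(
    similarity_metric = library$similarity_metric,
    frequencies_hz = library$frequencies,
    entries = lapply(seq_along(library$labels), function(i)
      list(label = library$labels[i],
           magnitudes = library$entries[[i]]$magnitudes))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  grid <- as.numeric(unlist(rec$frequencies_hz))
  entries <- lapply(rec$entries, function(e) {
    structure(list(frequencies = grid,
                   magnitudes = as.numeric(unlist(e$magnitudes)),
                   normalization = "unit-energy", window = "none",
                   n_samples = NA_integer_, sum_squares = NA_real_,
                   source = NA_character_, label = e$label),
              class = "pa_spectrum")
  })
  names(entries) <- vapply(rec$entries, `[[`, character(1), "label")
  fingerprint_library(entries)
}
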