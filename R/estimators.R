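#' Spectral signal-to-noise ratio
#'
#' Signal power against the broadband noise floor, both measured from the
#' one-sided spectrum: the signal-band power is converted to mean
#' time-domain power (`2 * sum_sig |X_k|^2 / n^2`) and divided by the
#' per-sample noise variance estimated from an out-of-band region
#' (`sum_noise |X_k|^2 / (M * n)` over `M` bins), so for a tone of RMS
#' `a` in white noise of RMS `b` the report is `20 log10(a / b)`.
#' Default bands: signal = dominant peak (searched in 1--10 MHz)
#' +/- 0.5 MHz; noise = 20--40 MHz, far enough above the photoacoustic
#' band to avoid leakage (for low-rate records the upper part of the grid
#' is used instead). The generator's noise calibration targets exactly
#' this measurement, so `estimate_snr(generate_signal(...))` recovers
#' `target_snr_db`.
#'
#' @param signal A `pa_signal`.
#' @param signal_band,noise_band Optional two-element bands in Hz; must be
#'   disjoint and within `[0, Nyquist]`.
#' @param cap_db Ceiling on the report: an (effectively) noiseless input
#'   returns `cap_db` instead of a divergent ratio.
#'
#' @return A `pa_snr` report: `snr_db`, `signal_band`, `noise_band`.
#' @export
estimate_snr <- function(signal, signal_band = NULL, noise_band = NULL,
                         cap_db = 200) {
  stopifnot(inherits(signal, "pa_signal"))
  nyq <- signal$sampling_rate / 2
  if (is.null(signal_band) || is.null(noise_band)) {
    sp <- compute_spectrum(signal)
    pk <- dominant_peak(sp, c(1e6, min(10e6, 0.9 * nyq)))
    bands <- snr_default_bands(pk$frequency, nyq)
    signal_band <- signal_band %||% bands$signal
    noise_band <- noise_band %||% bands$noise
  }
  if (any(c(signal_band, noise_band) < 0) ||
      any(c(signal_band, noise_band) > nyq))
    stop_pa("SNR bands must lie within [0, %.3g] Hz", nyq)
  if (max(signal_band[1], noise_band[1]) < min(signal_band[2], noise_band[2]))
    stop_pa("signal and noise bands must be disjoint")
  n <- length(signal$samples)
  freqs <- (seq_len(n %/% 2 + 1L) - 1L) * signal$sampling_rate / n
  m_noise <- sum(freqs >= noise_band[1] & freqs <= noise_band[2])
  ps <- band_power(signal$samples, signal$sampling_rate, signal_band)
  pn <- band_power(signal$samples, signal$sampling_rate, noise_band)
  if (ps == 0 && pn == 0)
    stop_pa("undefined SNR: zero power in both bands")
  p_signal_time <- 2 * ps / n^2        # mean signal power, mV^2
  sigma2_hat <- pn / (m_noise * n)     # noise variance per sample, mV^2
  # the cap is a ceiling: an (effectively) noiseless record reports
  # cap_db instead of a divergent ratio
  snr <- if (pn == 0) cap_db
         else min(cap_db, 10 * log10(p_signal_time / sigma2_hat))
  structure(list(snr_db = snr, signal_band = signal_band,
                 noise_band = noise_band),
            class = "pa_snr")
}

#' @export
print.pa_snr <- function(x, ...) {
  cat(sprintf("<pa_snr> %.2f dB (signal %.2f-%.2f MHz, noise %.1f-%.1f MHz)\n",
              x$snr_db, x$signal_band[1] / 1e6, x$signal_band[2] / 1e6,
              x$noise_band[1] / 1e6, x$noise_band[2] / 1e6))
  invisible(x)
}

#' Onset delay of a photoacoustic trace
#'
#' Photoacoustic readout is delayed relative to the excitation pulse by
#' the acoustic travel time from the particle to the resonator. The onset
#' is detected as the first run of `consecutive` samples whose absolute
#' value exceeds `k` times a robust noise scale (the median absolute
#' deviation of the trace); the reported delay is the time of the last
#' sample before that run, minus `reference_onset`, floored at zero.
#' Defaults `k = 5`, `consecutive = 3` reject isolated noise spikes.
#'
#' @param signal A `pa_signal`.
#' @param reference_onset Pulse emission time in seconds (default: the
#'   signal's trigger time).
#' @param k Threshold multiplier on the robust noise scale.
#' @param consecutive Number of consecutive supra-threshold samples
#'   required.
#'
#' @return Delay in seconds, or `NA_real_` when no onset is detected
#'   (distinct from a true zero delay).
#' @export
estimate_delay <- function(signal, reference_onset = NULL, k = 5,
                           consecutive = 3L) {
  stopifnot(inherits(signal, "pa_signal"))
  reference_onset <- reference_onset %||% signal$trigger_time
  x <- signal$samples
  if (all(x == 0)) return(NA_real_)
  sigma <- stats::mad(x, center = 0)
  thr <- k * sigma
  if (thr == 0) thr <- 1e-9 * max(abs(x))
  above <- abs(x) > thr
  if (consecutive > 1L) {
    run <- above
    for (s in seq_len(consecutive - 1L))
      run <- run & c(above[-seq_len(s)], rep(FALSE, s))
    first <- which(run)[1]
  } else {
    first <- which(above)[1]
  }
  if (is.na(first)) return(NA_real_)
  dt <- 1 / signal$sampling_rate
  onset <- (first - 2L) * dt # time of the last sample known below threshold
  max(0, onset - reference_onset)
}

#' Fit the linear region of a concentration response
#'
#' Ordinary least squares on the longest prefix of the (concentration,
#' amplitude) series that is still linear. Rule: starting from the full
#' series and shrinking, the first prefix (>= 3 points) whose OLS
#' coefficient of determination reaches `r2_min` is taken as the linear
#' region; a zero-variance (flat) prefix counts as perfectly linear with
#' slope 0. Saturated tails fail the r-squared bar and are excluded.
#'
#' @param points Data frame with concentration (fM) in the first column
#'   and amplitude (mV) in the second, or a two-column matrix; >= 4 points
#'   with distinct concentrations.
#' @param r2_min Linearity bar on the prefix r-squared (default 0.99).
#'
#' @return A `pa_concfit`: `slope` (mV mL fM^-1), `intercept` (mV),
#'   `linear_region` (indices), `r_squared`.
#' @export
fit_concentration_response <- function(points, r2_min = 0.99) {
  pts <- as.data.frame(points)
  if (ncol(pts) < 2L) stop_pa("points must have two columns")
  x <- as.numeric(pts[[1]])
  y <- as.numeric(pts[[2]])
  if (length(x) < 4L) stop_pa("need >= 4 points to identify a linear region")
  if (anyDuplicated(x)) stop_pa("concentrations must be distinct")
  ols <- function(m) {
    xs <- x[seq_len(m)]
    ys <- y[seq_len(m)]
    fit <- stats::lm.fit(cbind(1, xs), ys)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((ys - mean(ys))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    list(intercept = fit$coefficients[1], slope = fit$coefficients[2],
         r2 = r2)
  }
  for (m in seq(length(x), 3L)) {
    f <- ols(m)
    if (f$r2 >= r2_min) {
      return(structure(
        list(slope = unname(f$slope), intercept = unname(f$intercept),
             linear_region = seq_len(m), r_squared = f$r2),
        class = "pa_concfit"))
    }
  }
  stop_pa("no linear region of >= 3 points found (r-squared bar %.3g)",
          r2_min)
}

#' @export
print.pa_concfit <- function(x, ...) {
  cat(sprintf(
    "<pa_concfit> slope %.4g mV mL fM^-1, intercept %.4g mV, %d-point linear region, r^2 = %.4f\n",
    x$slope, x$intercept, length(x$linear_region), x$r_squared))
  invisible(x)
}
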