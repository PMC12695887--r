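test_that("compute_spectrum agrees with a direct O(N^2) DFT", {
  n <- 256
  fs <- 100e6
  x <- withr::with_seed(9, sin(2 * pi * 4e6 * (0:(n - 1)) / fs) +
                          0.3 * rnorm(n))
  sp <- compute_spectrum(raw_signal(x[1:n], fs))
  # brute-force DFT oracle
  k <- 0:(n %/% 2)
  direct <- vapply(k, function(kk)
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))), numeric(1))
  expect_equal(sp$magnitudes, direct, tolerance = 1e-9)
  expect_equal(sp$frequencies, k * fs / n)
})

test_that("a constant signal concentrates all magnitude at 0 Hz", {
  sp <- compute_spectrum(raw_signal(rep(2, 128), 12.5e6))
  expect_equal(sp$magnitudes[1], 2 * 128)
  expect_equal(max(sp$magnitudes[-1]), 0, tolerance = 1e-9)
})

test_that("Parseval's identity holds under the documented convention", {
  for (s in 1:10) {
    n <- sample(c(128, 250, 4096), 1)
    x <- withr::with_seed(s, rnorm(n))
    sig <- raw_signal(x, 50e6)
    expect_equal(spectrum_energy(compute_spectrum(sig)), sum(x^2),
                 tolerance = 1e-9)
  }
  expect_error(compute_spectrum(raw_signal(c(rep(0, 127), NA))),
               "non-finite")
})

test_that("dominant_peak finds the band argmax with a low-frequency tie rule", {
  freqs <- seq(0, 12.5e6, by = 0.1e6)
  mags <- numeric(length(freqs))
  mags[freqs == 4e6] <- 1
  expect_equal(dominant_peak(raw_spectrum(freqs, mags),
                             c(1e6, 10e6))$frequency, 4e6)

  tie <- numeric(length(freqs))
  tie[freqs == 3.9e6] <- 2
  tie[freqs == 4.1e6] <- 2
  expect_equal(dominant_peak(raw_spectrum(freqs, tie),
                             c(1e6, 10e6))$frequency, 3.9e6)

  # exhaustive-scan oracle on random spectra + positive rescale invariance
  for (s in 1:5) {
    m <- withr::with_seed(100 + s, runif(length(freqs)))
    band <- c(1e6, 10e6)
    got <- dominant_peak(raw_spectrum(freqs, m), band)
    inb <- which(freqs >= band[1] & freqs <= band[2])
    best <- inb[which.max(m[inb])]
    expect_equal(got$frequency, freqs[best])
    scaled <- dominant_peak(raw_spectrum(freqs, 7.3 * m), band)
    expect_equal(scaled$frequency, got$frequency)
  }

  expect_error(dominant_peak(raw_spectrum(freqs, mags), c(5e6, 4e6)), "band")
  expect_error(dominant_peak(raw_spectrum(freqs, mags), c(4e6, 4.05e6)),
               ">= 3")
})

test_that("SNR estimates match a time-domain RMS oracle for a noisy tone", {
  n <- 16384
  fs <- 100e6
  for (s in 1:3) {
    a_rms <- 1
    b <- c(0.05, 0.1, 0.3)[s]
    x <- withr::with_seed(s, sqrt(2) * a_rms * sin(2 * pi * 4e6 *
                                                     (0:(n - 1)) / fs) +
                            rnorm(n, 0, b))
    got <- estimate_snr(raw_signal(x, fs))$snr_db
    expect_lt(abs(got - 20 * log10(a_rms / b)), 1)
  }
})

test_that("SNR degenerates gracefully", {
  # bin-aligned undamped tone: zero leakage, so the noise band is empty
  n <- 1000
  tone <- raw_signal(sin(2 * pi * 4e6 * (0:(n - 1)) / 100e6), 100e6)
  expect_equal(estimate_snr(tone)$snr_db, 200)
  clean <- generate_signal(tone_template(),
                           acquisition_config(noise_rms = 0,
                                              target_snr_db = NULL))
  expect_error(estimate_snr(raw_signal(rep(0, 128), 100e6),
                            signal_band = c(3e6, 5e6),
                            noise_band = c(20e6, 40e6)),
               "undefined")
  expect_error(estimate_snr(clean, signal_band = c(3e6, 25e6),
                            noise_band = c(20e6, 40e6)), "disjoint")
})

test_that("SNR increases monotonically as generator noise decreases", {
  tpl <- default_templates("rbc_species")$sheep
  ladder <- c(0.2, 0.1, 0.05, 0.02, 0.01)
  means <- vapply(ladder, function(nr) {
    mean(vapply(1:10, function(s) {
      cfg <- acquisition_config(noise_rms = nr, target_snr_db = NULL,
                                seed = s)
      estimate_snr(generate_signal(tpl, cfg))$snr_db
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("onset delay recovers the configured travel time", {
  tpl <- default_templates("rbc_species")$sheep

  near <- generate_signal(tpl, acquisition_config(seed = 2))
  expect_lt(estimate_delay(near), 1 / near$sampling_rate)

  cfg <- acquisition_config(distance = 1.48e-3, seed = 2)
  expect_lt(abs(estimate_delay(generate_signal(tpl, cfg)) - 1e-6),
            1 / cfg$sampling_rate)

  expect_identical(estimate_delay(raw_signal(rep(0, 128), 100e6)), NA_real_)

  # cross-correlation oracle over 20 seeded random distances
  ref <- generate_signal(tpl, acquisition_config(noise_rms = 0,
                                                 target_snr_db = NULL,
                                                 seed = 1))
  dists <- withr::with_seed(77, runif(20, 0, 10e-3))
  for (i in seq_along(dists)) {
    cfg_i <- acquisition_config(distance = dists[i], seed = i)
    sig <- generate_signal(tpl, cfg_i, seed = 1)
    tau <- dists[i] / cfg_i$sound_speed
    dt <- 1 / cfg_i$sampling_rate
    expect_lt(abs(estimate_delay(sig) - tau), dt + 1e-12)
    cc <- vapply(0:round(12e-3 / 1480 / dt), function(lag) {
      m <- length(sig$samples) - lag
      sum(sig$samples[(lag + 1):(lag + m)] * ref$samples[1:m])
    }, numeric(1))
    lag_hat <- (which.max(cc) - 1) * dt
    expect_lt(abs(lag_hat - tau), dt + 1e-12)
  }
})

test_that("concentration fit recovers slope and excludes saturated tails", {
  exact <- data.frame(c = c(1, 2, 3, 4, 6), a = 2.5 * c(1, 2, 3, 4, 6))
  fit <- fit_concentration_response(exact)
  expect_equal(fit$slope, 2.5)
  expect_equal(fit$r_squared, 1)

  flat <- data.frame(c = 1:5, a = rep(3, 5))
  fit_flat <- fit_concentration_response(flat)
  expect_equal(fit_flat$slope, 0)
  expect_equal(fit_flat$intercept, 3)

  # saturated tail, noiseless: closed-form least squares on the true
  # linear subset is the oracle
  c_all <- 1:10
  a_all <- pmin(2.5 * c_all, 12.5)
  fit_sat <- fit_concentration_response(data.frame(c_all, a_all))
  expect_identical(fit_sat$linear_region, 1:5)
  lin <- fit_sat$linear_region
  sxy <- sum((c_all[lin] - mean(c_all[lin])) * (a_all[lin] - mean(a_all[lin])))
  sxx <- sum((c_all[lin] - mean(c_all[lin]))^2)
  expect_equal(fit_sat$slope, sxy / sxx)
  expect_equal(fit_sat$slope, 2.5)

  expect_error(fit_concentration_response(exact[1:3, ]), ">= 4")
  expect_error(fit_concentration_response(data.frame(c = c(1, 1, 2, 3),
                                                     a = 1:4)), "distinct")
})

test_that("spectral matching is exact, ranked and oracle-consistent", {
  lib <- build_fingerprint_library(default_templates("aunp_geometry"))

  self <- match_spectrum(lib$entries$nanorod, lib)
  expect_identical(self$label, "nanorod")
  expect_equal(self$similarity, 1.0, tolerance = 1e-12)

  # exact orthogonality needs compact support: use a toy library
  grid <- seq(0, 99, by = 1)
  toy <- fingerprint_library(list(
    a = raw_spectrum(grid, as.numeric(grid < 30)),
    b = raw_spectrum(grid, as.numeric(grid >= 30 & grid < 60))))
  ortho <- raw_spectrum(grid, as.numeric(grid >= 60))
  expect_identical(match_spectrum(ortho, toy)$similarity, 0)

  # 40 noisy queries vs an exhaustive pairwise-similarity oracle
  tpls <- default_templates("aunp_geometry")
  hits <- 0L
  for (g in seq_along(tpls)) {
    for (r in 1:10) {
      cfg <- acquisition_config(noise_rms = 0.02, target_snr_db = NULL,
                                seed = 1000L * g + r)
      q <- compute_spectrum(generate_signal(tpls[[g]], cfg),
                            normalization = "unit-energy")
      got <- match_spectrum(q, lib)
      qi <- stats::approx(q$frequencies, q$magnitudes,
                          xout = lib$frequencies, rule = 1)$y
      qi[is.na(qi)] <- 0
      sims <- vapply(lib$entries, function(e) {
        sum(qi * e$magnitudes) /
          sqrt(sum(qi^2) * sum(e$magnitudes^2))
      }, numeric(1))
      expect_identical(got$label, names(sims)[which.max(sims)])
      expect_equal(got$similarity, unname(max(sims)), tolerance = 1e-12)
      hits <- hits + (got$label == names(tpls)[g])
    }
  }
  expect_identical(hits, 40L)
})

test_that("cosine similarity is symmetric and maximal only at rescaling", {
  for (s in 1:10) {
    x <- withr::with_seed(s, runif(50))
    y <- withr::with_seed(s + 50, runif(50))
    cs <- pafingerprint:::cosine_similarity
    expect_equal(cs(x, y), cs(y, x))
    expect_equal(cs(x, 3.7 * x), 1, tolerance = 1e-12)
    expect_lt(cs(x, y), 1)
  }
})

test_that("spectra and libraries round-trip through text files", {
  tpl <- default_templates("rbc_species")$sheep
  sp <- compute_spectrum(generate_signal(tpl, acquisition_config(seed = 1)))
  f <- tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$frequencies, sp$frequencies)
  expect_equal(back$magnitudes, sp$magnitudes, tolerance = 1e-9)

  lib <- build_fingerprint_library(default_templates("aunp_geometry"),
                                   n_bins = 200)
  lf <- tempfile(fileext = ".json")
  write_library(lib, lf)
  lib2 <- read_library(lf)
  expect_identical(lib2$labels, lib$labels)
  expect_equal(lib2$entries$nanocube$magnitudes,
               lib$entries$nanocube$magnitudes, tolerance = 1e-12)
})
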