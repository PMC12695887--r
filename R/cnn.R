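#' Configuration of the 1-D convolutional feature extractor
#'
#' The extractor maps a preprocessed spectrum of `input_length` bins to a
#' `feature_dim`-dimensional latent feature: valid (unpadded)
#' convolutions whose kernels stride along the frequency axis and capture
#' local spectral patterns, ReLU, non-overlapping max pooling of width
#' `pool_width` after every convolution, flatten, and a fully connected
#' layer with ReLU. Defaults (two conv layers of width 9 x 16 channels and
#' 5 x 32 channels, pool width 4, 32-dimensional features) are small
#' enough to train in seconds on one CPU yet expressive enough for
#' five-class spectra.
#'
#' @param input_length Number of input spectrum bins.
#' @param conv_kernels List of `c(width, channels)` pairs, one per
#'   convolution layer.
#' @param pool_width Max-pooling window (non-overlapping); trailing
#'   positions that do not fill a window are dropped.
#' @param feature_dim Latent feature dimension D (>= 2).
#' @param seed Seed for reproducible weight initialization.
#'
#' @return A `pa_model_config`.
#' @export
model_config <- function(input_length = 256L,
                         conv_kernels = list(c(9L, 16L), c(5L, 32L)),
                         pool_width = 4L, feature_dim = 32L, seed = 1L) {
  if (!is_scalar_num(input_length) || input_length < 8)
    stop_pa("input_length must be >= 8 bins")
  if (!is_scalar_num(feature_dim) || feature_dim < 2)
    stop_pa("feature_dim must be >= 2")
  if (!is_scalar_num(pool_width) || pool_width < 1)
    stop_pa("pool_width must be >= 1")
  cfg <- structure(
    list(input_length = as.integer(input_length),
         conv_kernels = lapply(conv_kernels, as.integer),
         pool_width = as.integer(pool_width),
         feature_dim = as.integer(feature_dim),
         activation = "relu", seed = as.integer(seed)),
    class = "pa_model_config"
  )
  model_dims(cfg) # validates kernel widths against running length
  cfg
}

# Layer-by-layer lengths/channels implied by a config; errors if any
# kernel is wider than the map it convolves.
model_dims <- function(config) {
  len <- config$input_length
  chan <- 1L
  layers <- list()
  for (i in seq_along(config$conv_kernels)) {
    k <- config$conv_kernels[[i]]
    w <- k[1]
    cout <- k[2]
    if (w < 1 || cout < 1) stop_pa("conv layer %d: invalid width/channels", i)
    if (w > len)
      stop_pa("conv layer %d: kernel width %d exceeds input length %d",
              i, w, len)
    conv_len <- len - w + 1L
    pool_len <- conv_len %/% config$pool_width
    if (pool_len < 1L)
      stop_pa("conv layer %d: pooled length collapses to zero", i)
    layers[[i]] <- list(width = w, c_in = chan, c_out = cout,
                        conv_len = conv_len, pool_len = pool_len)
    len <- pool_len
    chan <- cout
  }
  list(layers = layers, flat_dim = len * chan,
       feature_dim = config$feature_dim)
}

#' Initialize the feature extractor
#'
#' He-scaled Gaussian weights, zero biases, drawn from the config seed;
#' identical seeds give bitwise-identical parameters.
#'
#' @param config A [model_config()].
#' @return A `pa_model`: `config`, `params`, `digest`.
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "pa_model_config"))
  dims <- model_dims(config)
  params <- withr::with_seed(config$seed, {
    conv <- lapply(dims$layers, function(ly) {
      fan_in <- ly$width * ly$c_in
      list(W = array(stats::rnorm(fan_in * ly$c_out) * sqrt(2 / fan_in),
                     dim = c(ly$width, ly$c_in, ly$c_out)),
           b = numeric(ly$c_out))
    })
    fc <- list(W = matrix(stats::rnorm(dims$flat_dim * config$feature_dim) *
                            sqrt(2 / dims$flat_dim),
                          dims$flat_dim, config$feature_dim),
               b = numeric(config$feature_dim))
    list(conv = conv, fc = fc)
  })
  structure(list(config = config, params = params,
                 digest = pa_digest(params)),
            class = "pa_model")
}

#' @export
print.pa_model <- function(x, ...) {
  dims <- model_dims(x$config)
  np <- sum(vapply(x$params$conv, function(l) length(l$W) + length(l$b),
                   numeric(1))) + length(x$params$fc$W) + length(x$params$fc$b)
  cat(sprintf("<pa_model> input %d bins -> %d features, %d conv layer(s), %d parameters\n",
              x$config$input_length, dims$feature_dim,
              length(dims$layers), np))
  invisible(x)
}

# Batch forward pass. X: n x input_length matrix. Returns the feature
# matrix (n x D) and, when keep_cache, the intermediates needed by
# cnn_backward().
cnn_forward <- function(params, config, X, keep_cache = FALSE) {
  n <- nrow(X)
  P <- config$pool_width
  A <- array(X, dim = c(n, ncol(X), 1L))
  cache <- list(layers = list())
  for (li in seq_along(params$conv)) {
    W <- params$conv[[li]]$W
    b <- params$conv[[li]]$b
    w <- dim(W)[1]
    cin <- dim(W)[2]
    cout <- dim(W)[3]
    lin <- dim(A)[2]
    lout <- lin - w + 1L
    cols <- array(0, dim = c(n, lout, w * cin))
    for (cc in seq_len(cin))
      for (j in seq_len(w))
        cols[, , (cc - 1L) * w + j] <- A[, j:(j + lout - 1L), cc]
    colm <- cols
    dim(colm) <- c(n * lout, w * cin)
    Wm <- W
    dim(Wm) <- c(w * cin, cout)
    Z <- colm %*% Wm
    Z <- Z + rep(b, each = n * lout)
    mask <- Z > 0
    R <- Z * mask
    lp <- lout %/% P
    Rarr <- array(R, dim = c(n, lout, cout))
    R4 <- Rarr[, seq_len(lp * P), , drop = FALSE]
    dim(R4) <- c(n, P, lp, cout)
    M <- R4[, 1, , , drop = TRUE]
    dim(M) <- c(n, lp, cout)
    idx <- array(1L, dim = c(n, lp, cout))
    if (P > 1L) {
      for (r in 2:P) {
        cand <- R4[, r, , , drop = TRUE]
        dim(cand) <- c(n, lp, cout)
        upd <- cand > M
        M[upd] <- cand[upd]
        idx[upd] <- r
      }
    }
    if (keep_cache)
      cache$layers[[li]] <- list(colm = colm, mask = mask, idx = idx,
                                 lin = lin, lout = lout, lp = lp,
                                 cin = cin, cout = cout, w = w)
    A <- M
  }
  lp <- dim(A)[2]
  cfin <- dim(A)[3]
  flat <- A
  dim(flat) <- c(n, lp * cfin)
  F0 <- flat %*% params$fc$W
  F0 <- F0 + rep(params$fc$b, each = n)
  fmask <- F0 > 0
  feats <- F0 * fmask
  if (keep_cache) {
    cache$flat <- flat
    cache$fmask <- fmask
    cache$final <- c(lp = lp, c = cfin)
    list(features = feats, cache = cache)
  } else {
    feats
  }
}

# Gradients of all parameters given dL/dfeatures. Mirrors cnn_forward.
cnn_backward <- function(params, config, cache, dfeat) {
  n <- nrow(dfeat)
  P <- config$pool_width
  dF0 <- dfeat * cache$fmask
  gfc <- list(W = crossprod(cache$flat, dF0), b = colSums(dF0))
  dflat <- dF0 %*% t(params$fc$W)
  dA <- dflat
  dim(dA) <- c(n, cache$final["lp"], cache$final["c"])
  gconv <- vector("list", length(params$conv))
  for (li in rev(seq_along(params$conv))) {
    ly <- cache$layers[[li]]
    # max-pool backward: route gradient to the argmax slot of each window
    dR4 <- array(0, dim = c(n, P, ly$lp, ly$cout))
    for (r in seq_len(P)) {
      sel <- ly$idx == r
      tmp <- array(0, dim = c(n, ly$lp, ly$cout))
      tmp[sel] <- dA[sel]
      dR4[, r, , ] <- tmp
    }
    dR <- array(0, dim = c(n, ly$lout, ly$cout))
    dim(dR4) <- c(n, ly$lp * P, ly$cout)
    dR[, seq_len(ly$lp * P), ] <- dR4
    dZ <- dR
    dim(dZ) <- c(n * ly$lout, ly$cout)
    dZ <- dZ * ly$mask
    gW <- crossprod(ly$colm, dZ)
    dim(gW) <- c(ly$w, ly$cin, ly$cout)
    gconv[[li]] <- list(W = gW, b = colSums(dZ))
    if (li > 1L) {
      Wm <- params$conv[[li]]$W
      dim(Wm) <- c(ly$w * ly$cin, ly$cout)
      dcols <- dZ %*% t(Wm)
      dim(dcols) <- c(n, ly$lout, ly$w * ly$cin)
      dA_in <- array(0, dim = c(n, ly$lin, ly$cin))
      for (cc in seq_len(ly$cin))
        for (j in seq_len(ly$w))
          dA_in[, j:(j + ly$lout - 1L), cc] <-
            dA_in[, j:(j + ly$lout - 1L), cc] + dcols[, , (cc - 1L) * ly$w + j]
      dA <- dA_in
    }
  }
  list(conv = gconv, fc = gfc)
}

#' Preprocess a spectrum for the feature extractor
#'
#' Crops the spectrum to `band`, linearly resamples it onto
#' `input_length` uniform bins, and scales to unit maximum (an all-zero
#' spectrum stays zero). Amplitude varies with concentration and laser
#' coupling, so classification keys on spectral shape, not scale.
#'
#' @param spectrum A `pa_spectrum`.
#' @param input_length Output length in bins.
#' @param band Frequency band (Hz) retained; default 0--12.5 MHz covers
#'   the photoacoustic peaks with margin.
#' @return Numeric vector of length `input_length` in `[0, 1]`.
#' @export
spectrum_to_input <- function(spectrum, input_length = 256L,
                              band = c(0, 12.5e6)) {
  rs <- resample_spectrum(spectrum, input_length, band)
  v <- rs$magnitudes
  m <- max(v)
  if (m > 0) v <- v / m
  v
}

#' Extract latent features from spectra
#'
#' Deterministic forward pass of the extractor. The spectrum (or numeric
#' vector) must already be on the model's input grid; use
#' [spectrum_to_input()] upstream.
#'
#' @param model A `pa_model`.
#' @param spectrum A `pa_spectrum` whose grid length equals
#'   `input_length`, or a numeric vector of that length.
#' @return Numeric feature vector of length `feature_dim`.
#' @export
extract_features <- function(model, spectrum) {
  stopifnot(inherits(model, "pa_model"))
  x <- if (inherits(spectrum, "pa_spectrum")) spectrum$magnitudes
       else as.numeric(spectrum)
  if (length(x) != model$config$input_length)
    stop_pa("input has %d bins; model expects %d (resample upstream)",
            length(x), model$config$input_length)
  if (!all(is.finite(x))) stop_pa("non-finite values in model input")
  drop(cnn_forward(model$params, model$config, matrix(x, nrow = 1)))
}

#' @rdname extract_features
#' @param spectra List of spectra/vectors; processed as one batch,
#'   elementwise identical to single calls.
#' @return `extract_features_batch()`: a `length(spectra) x feature_dim`
#'   matrix (zero rows for an empty list).
#' @export
extract_features_batch <- function(model, spectra) {
  stopifnot(inherits(model, "pa_model"), is.list(spectra))
  if (length(spectra) == 0L)
    return(matrix(numeric(0), 0, model$config$feature_dim))
  rows <- lapply(seq_along(spectra), function(i) {
    x <- spectra[[i]]
    x <- if (inherits(x, "pa_spectrum")) x$magnitudes else as.numeric(x)
    if (length(x) != model$config$input_length || !all(is.finite(x)))
      stop_pa("batch element %d: invalid input (length %d, model expects %d)",
              i, length(x), model$config$input_length)
    x
  })
  cnn_forward(model$params, model$config, do.call(rbind, rows))
}

#' Save and load a model checkpoint
#'
#' Single-file checkpoint (config + parameters + digest); loading
#' verifies the digest against the stored parameters.
#'
#' @param model A `pa_model`.
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pa_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pa_model")) stop_pa("%s is not a model checkpoint", path)
  if (!identical(pa_digest(model$params), model$digest))
    stop_pa("checkpoint digest mismatch: %s is corrupt", path)
  model
}
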