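#' Per-class prototype embeddings
#'
#' Prototypes `m_yj` are trainable points in the extractor's latent
#' space, `K` per class (default and study configuration: `K = 1`, one
#' representative embedding per class). A sample is classified as the
#' class of its nearest prototype in Euclidean distance.
#'
#' @param m Numeric matrix of prototypes, `(C * K) x D`, rows grouped by
#'   class (class-major order), or `C x D` for `K = 1`.
#' @param class_names Ordered class labels (C >= 2).
#' @param K Prototypes per class.
#' @return A `pa_prototypes`.
#' @export
prototype_set <- function(m, class_names, K = 1L) {
  m <- as.matrix(m)
  if (length(class_names) < 2L) stop_pa("need >= 2 classes")
  if (anyDuplicated(class_names)) stop_pa("class names must be unique")
  K <- as.integer(K)
  if (K < 1L) stop_pa("K must be >= 1")
  if (nrow(m) != length(class_names) * K)
    stop_pa("prototype matrix has %d rows; expected C*K = %d",
            nrow(m), length(class_names) * K)
  if (!all(is.finite(m))) stop_pa("prototypes must be finite")
  structure(list(m = m, class_names = as.character(class_names), K = K),
            class = "pa_prototypes")
}

#' @export
print.pa_prototypes <- function(x, ...) {
  cat(sprintf("<pa_prototypes> %d classes x K=%d in %d-D latent space\n",
              length(x$class_names), x$K, ncol(x$m)))
  invisible(x)
}

# Per-class Euclidean distances from one feature vector (K > 1: minimum
# over the class's prototypes).
class_distances <- function(feature, prototypes) {
  f <- as.numeric(feature)
  if (length(f) != ncol(prototypes$m))
    stop_pa("feature has length %d; prototypes are %d-dimensional",
            length(f), ncol(prototypes$m))
  if (!all(is.finite(f))) stop_pa("non-finite feature vector")
  d <- sqrt(rowSums(sweep(prototypes$m, 2, f)^2))
  if (prototypes$K > 1L) {
    cls <- rep(seq_along(prototypes$class_names), each = prototypes$K)
    d <- vapply(split(d, cls), min, numeric(1))
  }
  stats::setNames(as.numeric(d), prototypes$class_names)
}

#' Nearest-prototype classification
#'
#' Assigns a latent feature to the class of its nearest prototype
#' embedding (Euclidean distance over all `C * K` prototypes); ties
#' resolve to the lowest class index.
#'
#' @param feature Numeric feature vector of length D.
#' @param prototypes A [prototype_set()].
#' @return List with `class` and `distance`.
#' @export
classify <- function(feature, prototypes) {
  stopifnot(inherits(prototypes, "pa_prototypes"))
  d <- class_distances(feature, prototypes)
  i <- which.min(d)
  list(class = prototypes$class_names[i], distance = unname(d[i]))
}

#' Distance-softmax class probabilities
#'
#' `p(y | x) = exp(-d_y) / sum_k exp(-d_k)` with `d_y` the Euclidean
#' distance from the feature to class `y`'s prototype. Computed with a
#' min-distance shift before exponentiation, so the result is invariant
#' (to machine precision) under a common additive shift of all distances
#' and never under/overflows. The argmax always agrees with
#' [classify()].
#'
#' @inheritParams classify
#' @return A `pa_probs`: named `probabilities` summing to 1, plus
#'   `class_names`.
#' @export
class_probabilities <- function(feature, prototypes) {
  stopifnot(inherits(prototypes, "pa_prototypes"))
  d <- class_distances(feature, prototypes)
  e <- exp(-(d - min(d)))
  structure(list(probabilities = e / sum(e),
                 class_names = prototypes$class_names),
            class = "pa_probs")
}

#' @export
print.pa_probs <- function(x, ...) {
  p <- x$probabilities
  cat(sprintf("<pa_probs> %s\n",
              paste(sprintf("%s %.3f", names(p), p), collapse = ", ")))
  invisible(x)
}

#' Cross-entropy of a prototype prediction
#'
#' `CE = -log p(y | x)` in natural log, with the probability clamped at
#' `eps` so a vanishing probability yields a large finite loss.
#'
#' @param probabilities A `pa_probs` from [class_probabilities()].
#' @param y True class label (must be one of the class names).
#' @param eps Clamp for zero probabilities.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(probabilities, y, eps = 1e-12) {
  stopifnot(inherits(probabilities, "pa_probs"))
  if (!y %in% probabilities$class_names)
    stop_pa("unknown class '%s'", y)
  -log(max(probabilities$probabilities[[y]], eps))
}

#' Prototype loss
#'
#' Squared Euclidean distance between a latent feature and the prototype
#' of its true class (`K > 1`: the nearest prototype of that class). Zero
#' exactly when the feature coincides with the prototype; minimizing it
#' pulls same-class features onto one representative point, which is what
#' makes the classifier robust to spectral noise.
#'
#' @inheritParams classify
#' @param y True class label.
#' @return Non-negative scalar loss.
#' @export
prototype_loss <- function(feature, prototypes, y) {
  stopifnot(inherits(prototypes, "pa_prototypes"))
  ci <- match(y, prototypes$class_names)
  if (is.na(ci)) stop_pa("unknown class '%s'", y)
  f <- as.numeric(feature)
  if (length(f) != ncol(prototypes$m))
    stop_pa("feature has length %d; prototypes are %d-dimensional",
            length(f), ncol(prototypes$m))
  rows <- ((ci - 1L) * prototypes$K + 1L):(ci * prototypes$K)
  min(rowSums(sweep(prototypes$m[rows, , drop = FALSE], 2, f)^2))
}

#' Combined training loss
#'
#' `total = CE + lambda * PL`, the package's training objective: the
#' cross-entropy drives correct classification while the prototype term,
#' weighted by `lambda` (default 0.1), tightens same-class features
#' around their prototype.
#'
#' @param ce Cross-entropy term (>= 0).
#' @param pl Prototype-loss term (>= 0).
#' @param lambda Prototype-loss weight (>= 0).
#' @return A `pa_loss`: `ce`, `pl`, `lambda`, `total`.
#' @export
total_loss <- function(ce, pl, lambda = 0.1) {
  if (!is_scalar_num(ce) || ce < 0) stop_pa("ce must be >= 0")
  if (!is_scalar_num(pl) || pl < 0) stop_pa("pl must be >= 0")
  if (!is_scalar_num(lambda) || lambda < 0) stop_pa("lambda must be >= 0")
  structure(list(ce = ce, pl = pl, lambda = lambda,
                 total = ce + lambda * pl),
            class = "pa_loss")
}

#' Reproducible train/test split
#'
#' Disjoint, exhaustive split of a labelled dataset. Stratified (the
#' default) draws `round(train_fraction * n_c)` training samples per
#' class, preserving proportions exactly when divisible; unstratified
#' draws `round(train_fraction * n)` globally.
#'
#' @param dataset A `pa_dataset`.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param stratified Stratify by class (requires >= 2 samples per class).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return List with `train`, `test` (both `pa_dataset`, possibly empty)
#'   and `assignment` (data.frame: `index`, `label`, `set`).
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, stratified = TRUE,
                          seed = 1L) {
  stopifnot(inherits(dataset, "pa_dataset"))
  if (!is_scalar_num(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop_pa("train_fraction must lie in (0, 1)")
  labs <- dataset_labels(dataset)
  n <- length(labs)
  train_idx <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      unlist(lapply(dataset$class_names, function(cl) {
        idx <- which(labs == cl)
        if (length(idx) < 2L)
          stop_pa("class '%s' has %d sample(s); stratified split needs >= 2",
                  cl, length(idx))
        sample(idx, round(train_fraction * length(idx)))
      }))
    } else {
      sample(n, round(train_fraction * n))
    }
  })
  set <- rep("test", n)
  set[train_idx] <- "train"
  assignment <- data.frame(index = seq_len(n), label = labs, set = set,
                           stringsAsFactors = FALSE)
  subset_ds <- function(which_set) {
    idx <- which(set == which_set)
    pa_dataset(dataset$signals[idx], class_names = dataset$class_names,
               allow_empty = TRUE)
  }
  list(train = subset_ds("train"), test = subset_ds("test"),
       assignment = assignment)
}

#' Training configuration
#'
#' Hyperparameters of the joint optimization of extractor weights and
#' prototypes: Adam with the stated learning rate on minibatches of the
#' total loss.
#'
#' @param lambda Prototype-loss weight (default 0.1).
#' @param epochs Full passes over the training set (>= 0).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param train_fraction Train share of the 80/20-style split.
#' @param stratified Stratify the split by class.
#' @param seed Seed controlling the split, prototype init and shuffling.
#' @param prototype_init `"random"` (small-variance Gaussian, the
#'   default) or `"class_mean"` (warm start at the class means of the
#'   initial features).
#' @return A `pa_train_config`.
#' @export
train_config <- function(lambda = 0.1, epochs = 100L, batch_size = 16L,
                         learning_rate = 1e-3, train_fraction = 0.8,
                         stratified = TRUE, seed = 1L,
                         prototype_init = c("random", "class_mean")) {
  if (!is_scalar_num(lambda) || lambda < 0) stop_pa("lambda must be >= 0")
  if (!is_scalar_num(epochs) || epochs < 0) stop_pa("epochs must be >= 0")
  if (!is_scalar_num(batch_size) || batch_size < 1)
    stop_pa("batch_size must be >= 1")
  if (!is_scalar_num(learning_rate) || learning_rate <= 0)
    stop_pa("learning_rate must be positive")
  if (!is_scalar_num(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop_pa("train_fraction must lie in (0, 1)")
  structure(
    list(lambda = lambda, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, train_fraction = train_fraction,
         stratified = isTRUE(stratified), seed = as.integer(seed),
         prototype_init = match.arg(prototype_init)),
    class = "pa_train_config"
  )
}

# --- Adam over a flat list of arrays --------------------------------------

flatten_params <- function(params, M) {
  out <- list()
  for (li in seq_along(params$conv)) {
    out[[paste0("conv", li, ".W")]] <- params$conv[[li]]$W
    out[[paste0("conv", li, ".b")]] <- params$conv[[li]]$b
  }
  out$fc.W <- params$fc$W
  out$fc.b <- params$fc$b
  out$proto <- M
  out
}

unflatten_params <- function(flat, n_conv) {
  conv <- lapply(seq_len(n_conv), function(li)
    list(W = flat[[paste0("conv", li, ".W")]],
         b = flat[[paste0("conv", li, ".b")]]))
  list(params = list(conv = conv, fc = list(W = flat$fc.W, b = flat$fc.b)),
       M = flat$proto)
}

adam_step <- function(theta, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, state = state)
}

# Loss terms and gradients for one minibatch of features.
# F: nb x D; M: C x D (K = 1 during training); y: integer class indices.
proto_loss_grads <- function(F, M, y, lambda, eps_p = 1e-12) {
  nb <- nrow(F)
  C <- nrow(M)
  d2 <- pmax(outer(rowSums(F^2), rep(1, C)) +
               outer(rep(1, nb), rowSums(M^2)) - 2 * F %*% t(M), 0)
  d <- sqrt(d2)
  dsafe <- pmax(d, 1e-8)
  p <- exp(-(d - apply(d, 1, min)))
  p <- p / rowSums(p)
  iy <- cbind(seq_len(nb), y)
  ce <- -log(pmax(p[iy], eps_p))
  pl <- d2[iy]
  Y <- matrix(0, nb, C)
  Y[iy] <- 1
  G <- (Y - p) / dsafe
  dF <- (rowSums(G) * F - G %*% M + lambda * 2 * (F - M[y, , drop = FALSE])) / nb
  dM <- (-crossprod(G, F) + colSums(G) * M +
           lambda * 2 * (colSums(Y) * M - crossprod(Y, F))) / nb
  list(ce = mean(ce), pl = mean(pl), dF = dF, dM = dM,
       pred = max.col(-d, ties.method = "first"))
}

#' Train the prototype classifier
#'
#' End-to-end training of the spectral classifier: every signal is
#' converted to a one-sided FFT spectrum, cropped/resampled to the model
#' input grid and unit-max scaled; the data are split into training and
#' held-out test portions; then the extractor weights and the per-class
#' prototypes (`K = 1`) are jointly optimized with Adam on minibatches of
#' `CE + lambda * PL`. Fully deterministic given the seeds in the two
#' configs.
#'
#' @param dataset A `pa_dataset` with >= 2 classes.
#' @param config A [model_config()] for the extractor.
#' @param train A [train_config()].
#' @param input_band Frequency band (Hz) retained by
#'   [spectrum_to_input()].
#' @return A `pa_classifier`: trained `model`, `prototypes`, both
#'   configs, the split `assignment`, per-epoch `history` (ce, pl, total,
#'   train accuracy) and `class_names`.
#' @export
train_classifier <- function(dataset, config = model_config(),
                             train = train_config(),
                             input_band = c(0, 12.5e6)) {
  stopifnot(inherits(dataset, "pa_dataset"),
            inherits(config, "pa_model_config"),
            inherits(train, "pa_train_config"))
  if (length(dataset$class_names) < 2L)
    stop_pa("classification needs >= 2 classes")

  X <- t(vapply(dataset$signals, function(s)
    spectrum_to_input(compute_spectrum(s), config$input_length, input_band),
    numeric(config$input_length)))
  labs <- dataset_labels(dataset)
  y_all <- match(labs, dataset$class_names)

  sp <- split_dataset(dataset, train$train_fraction, train$stratified,
                      seed = train$seed)
  tr_idx <- sp$assignment$index[sp$assignment$set == "train"]
  Xtr <- X[tr_idx, , drop = FALSE]
  ytr <- y_all[tr_idx]
  ntr <- length(tr_idx)
  C <- length(dataset$class_names)
  D <- config$feature_dim

  model <- init_model(config)
  M <- withr::with_seed(pa_child_seed(train$seed, 101L), {
    if (train$prototype_init == "random") {
      matrix(stats::rnorm(C * D, sd = 0.01), C, D)
    } else {
      feats <- cnn_forward(model$params, config, Xtr)
      t(vapply(seq_len(C), function(ci) {
        rows <- which(ytr == ci)
        if (length(rows)) colMeans(feats[rows, , drop = FALSE])
        else stats::rnorm(D, sd = 0.01)
      }, numeric(D)))
    }
  })

  history <- data.frame(epoch = integer(0), ce = numeric(0),
                        pl = numeric(0), total = numeric(0),
                        train_accuracy = numeric(0))

  if (train$epochs > 0L && ntr > 0L) {
    theta <- flatten_params(model$params, M)
    state <- list(m = lapply(theta, function(a) a * 0),
                  v = lapply(theta, function(a) a * 0))
    t_step <- 0L
    withr::with_seed(pa_child_seed(train$seed, 202L), {
      for (ep in seq_len(train$epochs)) {
        perm <- sample(ntr)
        starts <- seq(1L, ntr, by = train$batch_size)
        ep_ce <- ep_pl <- 0
        ep_hit <- 0L
        for (s in starts) {
          bi <- perm[s:min(s + train$batch_size - 1L, ntr)]
          up <- unflatten_params(theta, length(config$conv_kernels))
          fw <- cnn_forward(up$params, config, Xtr[bi, , drop = FALSE],
                            keep_cache = TRUE)
          lg <- proto_loss_grads(fw$features, up$M, ytr[bi], train$lambda)
          if (!is.finite(lg$ce) || !is.finite(lg$pl))
            stop_pa("training diverged at epoch %d (non-finite loss)", ep)
          grads_net <- cnn_backward(up$params, config, fw$cache, lg$dF)
          grads <- flatten_params(grads_net, lg$dM)
          t_step <- t_step + 1L
          upd <- adam_step(theta, grads, state, train$learning_rate, t_step)
          theta <- upd$theta
          state <- upd$state
          nb <- length(bi)
          ep_ce <- ep_ce + lg$ce * nb
          ep_pl <- ep_pl + lg$pl * nb
          ep_hit <- ep_hit + sum(lg$pred == ytr[bi])
        }
        history[nrow(history) + 1L, ] <-
          list(ep, ep_ce / ntr, ep_pl / ntr,
               ep_ce / ntr + train$lambda * ep_pl / ntr, ep_hit / ntr)
      }
    })
    up <- unflatten_params(theta, length(config$conv_kernels))
    model$params <- up$params
    model$digest <- pa_digest(model$params)
    M <- up$M
  }

  structure(
    list(model = model,
         prototypes = prototype_set(M, dataset$class_names, K = 1L),
         model_config = config, train_config = train,
         input_band = input_band, split = sp$assignment,
         history = history, class_names = dataset$class_names),
    class = "pa_classifier"
  )
}

#' @export
print.pa_classifier <- function(x, ...) {
  cat(sprintf("<pa_classifier> %d classes (%s), %d-D latent space, %d epoch(s)\n",
              length(x$class_names), paste(x$class_names, collapse = ", "),
              ncol(x$prototypes$m), nrow(x$history)))
  if (nrow(x$history))
    cat(sprintf("  final loss %.4f (ce %.4f, pl %.4f), train accuracy %.3f\n",
                x$history$total[nrow(x$history)],
                x$history$ce[nrow(x$history)],
                x$history$pl[nrow(x$history)],
                x$history$train_accuracy[nrow(x$history)]))
  invisible(x)
}

# Preprocessed input rows for a classifier.
classifier_inputs <- function(object, signals) {
  t(vapply(signals, function(s)
    spectrum_to_input(compute_spectrum(s),
                      object$model_config$input_length, object$input_band),
    numeric(object$model_config$input_length)))
}

#' Predict classes for new photoacoustic signals
#'
#' Runs the full pipeline (spectrum, resampling, feature extraction,
#' nearest prototype) on one signal, a list of signals or a
#' `pa_dataset`. The predicted class always equals the argmax of the
#' distance-softmax probabilities.
#'
#' @param object A `pa_classifier` from [train_classifier()].
#' @param newdata A `pa_signal`, list of `pa_signal`s, or `pa_dataset`.
#' @param ... Unused.
#' @return List with `class` (character vector) and `probabilities`
#'   (matrix, one row per signal, columns named by class).
#' @export
predict.pa_classifier <- function(object, newdata, ...) {
  signals <- if (inherits(newdata, "pa_signal")) list(newdata)
             else if (inherits(newdata, "pa_dataset")) newdata$signals
             else newdata
  stopifnot(is.list(signals), length(signals) >= 1L)
  for (s in signals) stopifnot(inherits(s, "pa_signal"))
  X <- classifier_inputs(object, signals)
  feats <- cnn_forward(object$model$params, object$model_config, X)
  cls <- character(nrow(feats))
  probs <- matrix(0, nrow(feats), length(object$class_names),
                  dimnames = list(NULL, object$class_names))
  for (i in seq_len(nrow(feats))) {
    cls[i] <- classify(feats[i, ], object$prototypes)$class
    probs[i, ] <- class_probabilities(feats[i, ], object$prototypes)$probabilities
  }
  list(class = cls, probabilities = probs)
}

#' Persist and restore a trained classifier
#'
#' One-file archive (extractor checkpoint, prototype matrix, configs,
#' split record, history); the extractor digest is verified on load.
#'
#' @param classifier A `pa_classifier`.
#' @param path Archive file path.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pa_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pa_classifier"))
    stop_pa("%s is not a classifier archive", path)
  if (!identical(pa_digest(obj$model$params), obj$model$digest))
    stop_pa("classifier archive digest mismatch: %s is corrupt", path)
  obj
}
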