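#' PCA projection for feature visualization
#'
#' Mean-centred projection onto the top principal axes (no scaling), used
#' to contrast raw spectral features with learned latent features: raw
#' spectra of similar classes project to intermingled point clouds while
#' prototype-trained features form well-separated clusters. Sign
#' convention: each axis is flipped, if needed, so its largest-magnitude
#' loading is positive, making projections reproducible.
#'
#' @param features Numeric matrix (rows = samples) or list of equal-length
#'   numeric vectors; needs `n >= n_components + 1` rows.
#' @param n_components Number of components returned (default 2).
#' @param labels Optional per-row labels carried into the result.
#' @return A `pa_projection`: `coordinates`
#'   (`n x n_components`), `explained_variance_fractions`, `labels`,
#'   `degenerate` flag (all-zero variance input projects to zeros).
#' @export
pca_project <- function(features, n_components = 2L, labels = NULL) {
  X <- if (is.list(features) && !is.data.frame(features))
    do.call(rbind, lapply(features, as.numeric)) else as.matrix(features)
  if (!all(is.finite(X))) stop_pa("features must be finite")
  n_components <- as.integer(n_components)
  if (nrow(X) < n_components + 1L)
    stop_pa("need at least n_components + 1 = %d rows, got %d",
            n_components + 1L, nrow(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-300)) {
    return(structure(
      list(coordinates = matrix(0, nrow(X), n_components),
           explained_variance_fractions = rep(0, n_components),
           labels = labels, degenerate = TRUE),
      class = "pa_projection"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  if (k < n_components)
    coords <- cbind(coords, matrix(0, nrow(X), n_components - k))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  evk <- c(ev, rep(0, n_components))[seq_len(n_components)]
  structure(
    list(coordinates = unname(coords),
         explained_variance_fractions = evk,
         labels = labels, degenerate = FALSE),
    class = "pa_projection"
  )
}

#' @export
print.pa_projection <- function(x, ...) {
  cat(sprintf("<pa_projection> %d points x %d components; explained %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fractions),
                    collapse = " + ")))
  invisible(x)
}

#' Mean silhouette of a labelled embedding
#'
#' Standard silhouette statistic (Euclidean metric): for each point,
#' `s = (b - a) / max(a, b)` with `a` the mean distance to its own class
#' and `b` the smallest mean distance to another class; the mean over all
#' points quantifies how well-separated the class clusters are
#' (1 = ideal, ~0 = intermingled).
#'
#' @param coordinates Numeric matrix of embedded points (rows = samples).
#' @param labels Class label per row; >= 2 classes, each with >= 2
#'   points.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(coordinates, labels) {
  X <- as.matrix(coordinates)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop_pa("labels length %d does not match %d rows", length(labels),
            nrow(X))
  tab <- table(labels)
  if (length(tab) < 2L) stop_pa("silhouette needs >= 2 classes")
  if (any(tab < 2L))
    stop_pa("singleton class '%s' not allowed", names(tab)[tab < 2][1])
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Evaluate a trained classifier on a test set
#'
#' Predicts every test signal, assembles the confusion matrix (rows =
#' true class), accuracy and per-class recall, and computes mean
#' silhouettes on 2-D PCA projections of both the raw spectral inputs
#' and the learned features of the same test samples — the quantitative
#' version of the raw-vs-learned PCA contrast.
#'
#' @param classifier A `pa_classifier`.
#' @param test_set A non-empty `pa_dataset` whose classes are a subset of
#'   the classifier's.
#' @return A `pa_report`: `confusion`, `accuracy`, `per_class_recall`,
#'   `silhouette_raw`, `silhouette_learned` (the silhouettes are `NA`
#'   when the test set cannot support them, e.g. singleton classes).
#' @export
evaluate <- function(classifier, test_set) {
  stopifnot(inherits(classifier, "pa_classifier"),
            inherits(test_set, "pa_dataset"))
  if (length(test_set$signals) == 0L) stop_pa("empty test set")
  labs <- dataset_labels(test_set)
  if (!all(labs %in% classifier$class_names))
    stop_pa("test classes outside the classifier's: %s",
            paste(setdiff(labs, classifier$class_names), collapse = ", "))

  pred <- predict(classifier, test_set)
  cls <- classifier$class_names
  confusion <- table(factor(labs, levels = cls),
                     factor(pred$class, levels = cls))
  names(dimnames(confusion)) <- c("true", "predicted")
  accuracy <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)

  X <- classifier_inputs(classifier, test_set$signals)
  feats <- cnn_forward(classifier$model$params, classifier$model_config, X)
  sil <- function(mat) {
    ok <- length(unique(labs)) >= 2L && all(table(labs) >= 2L) &&
      nrow(mat) >= 3L
    if (!ok) return(NA_real_)
    silhouette_score(pca_project(mat, 2L)$coordinates, labs)
  }
  structure(
    list(confusion = confusion, accuracy = accuracy,
         per_class_recall = recall,
         silhouette_raw = sil(X), silhouette_learned = sil(feats)),
    class = "pa_report"
  )
}

#' @export
print.pa_report <- function(x, ...) {
  cat(sprintf("<pa_report> accuracy %.3f; silhouette raw %.3f -> learned %.3f\n",
              x$accuracy, x$silhouette_raw, x$silhouette_learned))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `pa_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pa_report"))
  rec <- list(
    accuracy = report$accuracy,
    per_class_recall = as.list(report$per_class_recall),
    silhouette_raw = report$silhouette_raw,
    silhouette_learned = report$silhouette_learned,
    confusion = list(classes = rownames(report$confusion),
                     counts = unclass(unname(report$confusion)))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
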